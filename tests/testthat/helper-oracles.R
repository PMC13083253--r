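# Independent oracles and small fixture builders used across the suite.

# Explicit penalized log-likelihood (independent of the package's C++ path).
pen_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  w <- p * (1 - p)
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  ld <- determinant(crossprod(X, X * w), logarithm = TRUE)$modulus
  ll + 0.5 * as.numeric(ld)
}

# Brute-force maximizer of the penalized likelihood by iterative dense grid
# refinement (vectorized over the grid; final spacing < 2e-4).
oracle_firth_grid <- function(X, y, half_width = 4, k = 21L, rounds = 7L) {
  p <- ncol(X)
  cols <- list()
  for (i in seq_len(p)) for (j in seq_len(i))
    cols[[length(cols) + 1L]] <- X[, i] * X[, j]
  XX <- do.call(cbind, cols)
  # vectorized determinants from the lower-triangle entry rows
  # (entry order for p=3: a11, a21, a22, a31, a32, a33)
  det_vec <- function(E) {
    if (p == 1L) return(E[1, ])
    if (p == 2L) return(E[1, ] * E[3, ] - E[2, ]^2)
    E[1, ] * (E[3, ] * E[6, ] - E[5, ]^2) -
      E[2, ] * (E[2, ] * E[6, ] - E[5, ] * E[4, ]) +
      E[4, ] * (E[2, ] * E[5, ] - E[3, ] * E[4, ])
  }
  center <- numeric(p)
  w <- half_width
  for (r in seq_len(rounds)) {
    axes <- lapply(center, function(c0) seq(c0 - w, c0 + w, length.out = k))
    grid <- as.matrix(expand.grid(axes))
    eta <- X %*% t(grid)
    pr <- plogis(eta)
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    ll <- colSums(y * log(pr) + (1 - y) * log(1 - pr))
    wts <- pr * (1 - pr)
    ent <- crossprod(XX, wts)                    # entries x grid-points
    dets <- det_vec(ent)
    ok <- dets > 0
    obj <- ifelse(ok, ll + 0.5 * log(pmax(dets, 1e-300)), -Inf)
    center <- grid[which.max(obj), ]
    w <- 2 * (2 * w / (k - 1))
  }
  center
}

# Full-enumeration exact HWE oracle: explicit multinomial-coefficient
# probabilities over every heterozygote configuration.
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n_bb + n_ab
  nm <- min(na, nb)
  if (nm == 0) return(1)
  hets <- seq(nm %% 2, nm, by = 2)
  pr <- vapply(hets, function(h) {
    hom_min <- (nm - h) / 2
    hom_maj <- n - h - hom_min
    exp(lfactorial(n) - lfactorial(hom_min) - lfactorial(h) -
          lfactorial(hom_maj) + h * log(2) +
          lfactorial(nm) + lfactorial(2 * n - nm) - lfactorial(2 * n))
  }, 0)
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Cox partial likelihood (Breslow form; valid oracle when times are untied).
oracle_cox_grid <- function(time, event, x, grid = seq(-4, 4, by = 1e-3)) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  pll <- vapply(grid, function(b) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    s
  }, 0)
  grid[which.max(pll)]
}

exact_binom_band <- function(n, p = 0.05, conf = 0.99) {
  c(qbinom((1 - conf) / 2, n, p), qbinom(1 - (1 - conf) / 2, n, p)) / n
}

# Small deterministic case-control table with standard covariate columns.
toy_samples <- function(n, seed = 42, n_cases = round(n / 6)) {
  set.seed(seed)
  data.frame(sample_id = sprintf("T%04d", seq_len(n)),
             phenotype = ifelse(seq_len(n) <= n_cases, 2L, 1L),
             sex = rep_len(c(1L, 2L), n),
             cohort = rep_len(c("A", "B"), n),
             supercohort = rep_len(c("WGS", "WXS"), n),
             technology = rep_len(c("WGS", "WXS"), n),
             matrix(rnorm(n * 10), n, 10,
                    dimnames = list(NULL, paste0("PC", 1:10))),
             syn_count = rpois(n, 40))
}
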