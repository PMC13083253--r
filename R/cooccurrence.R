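# Oligogenic dose-response modelling, permutation co-occurrence testing,
# pairwise interaction models and co-occurrence power simulation.

#' Oligogenic dose-response scan
#'
#' Groups samples by the number of distinct qualifying variants carried
#' (heterozygous and homozygous genotypes both count as a single event; at
#' `level = "gene"` several variants within one gene count once) and fits
#' a Firth model per category against the 0-variant reference group with
#' the standard covariates. A progressively increasing OR across
#' categories is the signature of cumulative (additive) oligogenic risk.
#'
#' @param G samples x variants dosage matrix.
#' @param samples sample table.
#' @param qualifying qualifying variant ids.
#' @param variants variant table (needed for `level = "gene"`).
#' @param level count distinct variants or distinct genes.
#' @param n_pcs PCs to adjust for.
#' @param max_category categories above this are pooled into it.
#' @return data frame: one row per category >= 1 present in the data, with
#'   `n_cases`, `n_controls`, `or_`, `p`; empty categories are omitted.
#' @export
dose_response_scan <- function(G, samples, qualifying, variants = NULL,
                               level = c("variant", "gene"), n_pcs = 10,
                               max_category = Inf) {
  level <- match.arg(level)
  if (length(qualifying) == 0L) {
    return(data.frame(category = integer(), n_cases = integer(),
                      n_controls = integer(), or_ = numeric(),
                      p = numeric()))
  }
  Gq <- G[, qualifying, drop = FALSE]
  carried <- !is.na(Gq) & Gq >= 1L
  if (level == "gene") {
    stopifnot(!is.null(variants))
    gene_of <- variants$gene[match(qualifying, variants$variant_id)]
    counts <- integer(nrow(G))
    for (g in unique(gene_of)) {
      cols <- which(gene_of == g)
      counts <- counts + (rowSums(carried[, cols, drop = FALSE]) > 0L)
    }
  } else {
    counts <- rowSums(carried)
  }
  counts <- pmin(counts, max_category)

  covars0 <- covariate_matrix(samples, n_pcs = n_pcs)
  ok <- complete.cases(covars0) & !is.na(samples$phenotype)
  y <- as.numeric(samples$phenotype == 2L)
  out <- NULL
  for (k in sort(unique(counts[counts >= 1L]))) {
    sel <- ok & counts %in% c(0L, k)
    yk <- y[sel]
    xk <- as.numeric(counts[sel] == k)
    n_cases <- sum(xk == 1 & yk == 1)
    n_controls <- sum(xk == 1 & yk == 0)
    fit <- tryCatch({
      X <- cbind(`(Intercept)` = 1, category = xk,
                 covars0[sel, , drop = FALSE])
      penalized_lr_test(X, yk, index = 2L)
    }, error = function(e) NULL)
    out <- rbind(out, data.frame(
      category = k, n_cases = n_cases, n_controls = n_controls,
      or_ = if (is.null(fit)) NA_real_ else exp(unname(fit$fit$beta[2L])),
      p = if (is.null(fit)) NA_real_ else fit$p))
  }
  out
}

#' Permutation test for co-occurrence of two variants
#'
#' Among samples (typically cases) with non-missing genotypes for both
#' variants, compares the observed co-carrier count to a null built by
#' shuffling one carrier vector relative to the other `B` times. Empirical
#' p-values use the add-one correction, so they are never zero:
#' `p_excess = (1 + #{null >= obs}) / (B + 1)`; `p_depletion` analogously
#' with `<=`; `p_two = min(1, 2 min(p_excess, p_depletion))`.
#'
#' @param carriers_a,carriers_b carrier status vectors (logical, or dosage
#'   vectors with `NA` for missing genotypes).
#' @param B number of permutations.
#' @param seed RNG seed.
#' @return list with `n_informative`, `observed`, `expected` (mean null
#'   co-count), `p_excess`, `p_depletion`, `p_two`, `B`, `seed`.
#' @export
pair_cooccurrence_perm <- function(carriers_a, carriers_b, B = 100000L,
                                   seed = 1L) {
  stopifnot(length(carriers_a) == length(carriers_b), B >= 1L)
  ok <- !is.na(carriers_a) & !is.na(carriers_b)
  ca <- as.logical(carriers_a[ok] >= 1)
  cb <- as.logical(carriers_b[ok] >= 1)
  n <- sum(ok)
  obs <- sum(ca & cb)
  if (!any(ca) || !any(cb)) {
    warning("a carrier set is empty; co-occurrence test degenerate")
    return(list(n_informative = n, observed = obs, expected = 0,
                p_excess = 1, p_depletion = 1, p_two = 1, B = B,
                seed = seed))
  }
  null_counts <- .run_seeded(seed, {
    vapply(seq_len(B), function(b) sum(ca[sample.int(n)] & cb), 1L)
  })
  p_exc <- (1 + sum(null_counts >= obs)) / (B + 1)
  p_dep <- (1 + sum(null_counts <= obs)) / (B + 1)
  list(n_informative = n, observed = obs, expected = mean(null_counts),
       p_excess = p_exc, p_depletion = p_dep,
       p_two = min(1, 2 * min(p_exc, p_dep)), B = B, seed = seed)
}

#' Pairwise interaction model for two variants
#'
#' Fits, in the full case-control cohort, the 16-coefficient Firth model
#' `status ~ var1 + var2 + var1:var2 + sex + synonymous count + PC1..PC10`
#' and tests the interaction coefficient with the penalized LRT. Under a
#' purely multiplicative (log-additive) joint effect the interaction term
#' is zero.
#'
#' @param G samples x variants dosage matrix.
#' @param samples sample table.
#' @param var_a,var_b variant ids (columns of `G`).
#' @param n_pcs PCs to adjust for (default 10, giving 16 columns).
#' @return list with `beta` (named coefficient vector),
#'   `interaction_beta`, `p_interaction`, `n`.
#' @export
pair_interaction_test <- function(G, samples, var_a, var_b, n_pcs = 10) {
  ga <- G[, var_a]
  gb <- G[, var_b]
  covars0 <- covariate_matrix(samples, n_pcs = n_pcs)
  ok <- !is.na(ga) & !is.na(gb) & complete.cases(covars0) &
    !is.na(samples$phenotype)
  ga <- ga[ok]; gb <- gb[ok]
  y <- as.numeric(samples$phenotype == 2L)[ok]
  if (sum(ga) == 0 || all(ga == max(ga))) stop("variant ", var_a, " is monomorphic")
  if (sum(gb) == 0 || all(gb == max(gb))) stop("variant ", var_b, " is monomorphic")
  inter <- ga * gb
  if (all(inter == inter[1]))
    stop("interaction inestimable: no variation in the joint carrier term")
  cv <- covars0[ok, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, var1 = ga, var2 = gb, var1_var2 = inter,
             sex = cv[, "sex"], syn_count = cv[, "syn_count"],
             cv[, grep("^PC", colnames(cv)), drop = FALSE])
  lrt <- penalized_lr_test(X, y, index = 4L)
  list(beta = lrt$fit$beta, interaction_beta = unname(lrt$fit$beta[4L]),
       p_interaction = lrt$p, n = sum(ok))
}

#' Power simulation for pairwise co-occurrence tests
#'
#' Draws `nsim` joint carrier tables from the multinomial implied by the
#' two carrier frequencies and a co-occurrence odds ratio (a Plackett-type
#' 2x2 cell solution), applies the two-sided Fisher exact test of
#' independence to each and reports the rejection fraction.
#'
#' @param freq_a,freq_b carrier frequencies in (0, 1).
#' @param co_or co-occurrence odds ratio (> 0).
#' @param n number of samples per simulation.
#' @param alpha significance level.
#' @param nsim number of simulations.
#' @param seed RNG seed.
#' @return power (fraction of simulations with p < `alpha`).
#' @export
cooccurrence_power <- function(freq_a, freq_b, co_or, n, alpha = 0.05,
                               nsim = 10000L, seed = 1L) {
  stopifnot(freq_a > 0, freq_a < 1, freq_b > 0, freq_b < 1, co_or > 0)
  p11 <- if (abs(co_or - 1) < 1e-12) freq_a * freq_b else {
    s <- 1 + (freq_a + freq_b) * (co_or - 1)
    (s - sqrt(s^2 - 4 * co_or * (co_or - 1) * freq_a * freq_b)) /
      (2 * (co_or - 1))
  }
  p10 <- freq_a - p11
  p01 <- freq_b - p11
  p00 <- 1 - p11 - p10 - p01
  if (min(p11, p10, p01, p00) < -1e-12)
    stop("carrier frequencies and co-occurrence OR are incompatible")
  probs <- pmax(c(p11, p10, p01, p00), 0)
  .run_seeded(seed, {
    draws <- rmultinom(nsim, n, probs)
    rej <- vapply(seq_len(nsim), function(i) {
      tab <- matrix(c(draws[1, i], draws[2, i], draws[3, i], draws[4, i]),
                    2, 2, byrow = TRUE)
      fisher.test(tab)$p.value < alpha
    }, NA)
    mean(rej)
  })
}
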