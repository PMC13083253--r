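# Variant-level quality control: exact Hardy-Weinberg test, rule-based
# flags (per-supercohort call rate, HWE in controls, long INDELs, spanning
# deletions), the control-control batch-effect scan, and duplicate-pair
# concordance.

#' Exact conditional Hardy-Weinberg equilibrium test
#'
#' Conditional on the observed allele counts, the probability of each
#' possible heterozygote count is hypergeometric-type:
#' \eqn{P(n_{het}) \propto n! \, 2^{n_{het}} / (n_{hom.minor}! \, n_{het}! \,
#' n_{hom.major}!)}. The p-value sums the probabilities of all heterozygote
#' configurations no more probable than the observed one. Monomorphic
#' variants return p = 1. Preferable to the chi-square test for rare
#' variants, where expected cell counts are tiny.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return exact p-value.
#' @examples
#' hwe_exact_test(2, 0, 2)  # 6/70
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one genotype required")
  n_minor <- min(2 * n_hom_alt + n_het, 2 * n_hom_ref + n_het)
  if (n_minor == 0L) return(1)
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    h * log(2) - lgamma(hom_min + 1) - lgamma(h + 1) - lgamma(hom_maj + 1)
  }, 0)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- prob[match(n_het, hets)]
  if (is.na(obs)) stop("observed heterozygote count inconsistent with allele counts")
  sum(prob[prob <= obs * (1 + 1e-12)])
}

#' Variant quality-control flags
#'
#' Applies, per variant: the per-supercohort call-rate rule (fail if the
#' genotyping rate is below `call_rate` in any supercohort), the exact HWE
#' test among controls (chromosome X among female controls only), the long
#' INDEL rule (length > `max_indel_len`), the spanning-deletion rule
#' (ALT `"*"`), and optionally the batch-scan min-P rule when a
#' [control_control_scan()] result is supplied.
#'
#' @param G samples x variants dosage matrix.
#' @param variants variant table (`variant_id`, `chrom`, `alt`, `vtype`,
#'   `length`).
#' @param samples sample table (`phenotype`, `sex`, `supercohort`).
#' @param thresholds list: `call_rate` (0.9), `hwe_p` (1e-4),
#'   `max_indel_len` (50), `batch_min_p` (1e-4).
#' @param batch_min_p optional per-variant minimum p from the
#'   control-control scan.
#' @return data frame of per-variant flags, the batch `min_p` used, and the
#'   conjunction `pass`.
#' @export
variant_qc_mask <- function(G, variants, samples,
                            thresholds = list(), batch_min_p = NULL) {
  th <- utils::modifyList(list(call_rate = 0.9, hwe_p = 1e-4,
                               max_indel_len = 50, batch_min_p = 1e-4),
                          thresholds)
  stopifnot(ncol(G) == nrow(variants), nrow(G) == nrow(samples))
  cr <- supercohort_call_rates(G, samples$supercohort)
  call_rate_fail <- apply(as.matrix(cr) < th$call_rate, 1, any)

  ctrl <- samples$phenotype == 1L
  hwe_fail <- vapply(seq_len(nrow(variants)), function(v) {
    rows <- ctrl
    if (variants$chrom[v] == "X") rows <- ctrl & samples$sex == 2L
    g <- G[rows, v]
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(FALSE)
    p <- hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
    p < th$hwe_p
  }, NA)

  length_fail <- variants$vtype == "INDEL" & variants$length > th$max_indel_len
  spanning_del_fail <- variants$alt == "*"
  if (is.null(batch_min_p)) batch_min_p <- rep(NA_real_, nrow(variants))
  batch_fail <- !is.na(batch_min_p) & batch_min_p < th$batch_min_p

  data.frame(variant_id = variants$variant_id,
             call_rate_fail = call_rate_fail, hwe_fail = hwe_fail,
             length_fail = length_fail,
             spanning_del_fail = spanning_del_fail,
             batch_fail = batch_fail, min_p = batch_min_p,
             pass = !(call_rate_fail | hwe_fail | length_fail |
                        spanning_del_fail | batch_fail))
}

#' Control-control batch-effect scan
#'
#' Within controls, tests each variant's dosage against membership of each
#' control cohort (cohorts with fewer than `min_cohort_size` controls are
#' merged into one pseudo-cohort) using Firth regression adjusted for sex
#' and the first four PCs. The per-variant minimum p-value over cohort
#' contrasts flags variants whose allele counts track cohort membership —
#' the signature of batch-specific calling artifacts.
#'
#' @param G samples x variants dosage matrix.
#' @param samples sample table (`phenotype`, `cohort`, `sex`, PCs).
#' @param n_pcs number of PCs to adjust for (default 4).
#' @param min_cohort_size cohorts with fewer controls are merged.
#' @return data frame `variant_id`, `min_p`, `n_contrasts`.
#' @export
control_control_scan <- function(G, samples, n_pcs = 4,
                                 min_cohort_size = 100) {
  ctrl <- samples$phenotype == 1L
  sm <- samples[ctrl, , drop = FALSE]
  Gc <- G[ctrl, , drop = FALSE]
  tab <- table(sm$cohort)
  coh <- as.character(sm$cohort)
  small <- names(tab)[tab < min_cohort_size]
  if (length(small) > 1L) coh[coh %in% small] <- "__MERGED__"
  cohorts <- unique(coh)
  if (length(cohorts) < 2L)
    stop("nothing to contrast: fewer than two control cohorts after merging")

  covars <- covariate_matrix(sm, n_pcs = n_pcs, syn_count = NULL)
  covars <- covars[, colnames(covars) != "syn_count", drop = FALSE]
  pmat <- matrix(NA_real_, ncol(G), length(cohorts))
  for (k in seq_along(cohorts)) {
    yk <- as.numeric(coh == cohorts[k])
    if (all(yk == 0) || all(yk == 1)) next
    X0 <- .validate_design(cbind(`(Intercept)` = 1, covars), yk)
    warm <- unname(fit_firth(X0, yk)$beta)
    for (v in seq_len(ncol(G))) {
      g <- Gc[, v]
      ok <- !is.na(g)
      if (sum(g[ok]) == 0L || all(g[ok] == max(g[ok]))) next
      X <- cbind(`(Intercept)` = 1, dose = g[ok], covars[ok, , drop = FALSE])
      pmat[v, k] <- tryCatch(
        .firth_lrt_core(X, yk[ok], index = 2L,
                        init = c(warm[1L], 0, warm[-1L]))$p,
        error = function(e) NA_real_)
    }
  }
  min_p <- apply(pmat, 1, function(r)
    if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
  data.frame(variant_id = colnames(G), min_p = min_p,
             n_contrasts = length(cohorts))
}

#' Genotype concordance across duplicate pairs
#'
#' @param G samples x variants dosage matrix.
#' @param pairs data frame of duplicate pairs (`sample_a`, `sample_b`).
#' @return data frame `variant_id`, `concordance` (fraction of pairs with
#'   equal non-missing genotypes; `NA` where no pair is informative) and
#'   `n_informative`.
#' @export
duplicate_concordance <- function(G, pairs) {
  if (!all(c(pairs$sample_a, pairs$sample_b) %in% rownames(G)))
    stop("pair references unknown sample id")
  A <- G[pairs$sample_a, , drop = FALSE]
  B <- G[pairs$sample_b, , drop = FALSE]
  inf <- !is.na(A) & !is.na(B)
  n_inf <- colSums(inf)
  eq <- colSums(inf & (A == B), na.rm = TRUE)
  data.frame(variant_id = colnames(G),
             concordance = ifelse(n_inf > 0, eq / n_inf, NA_real_),
             n_informative = n_inf)
}
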