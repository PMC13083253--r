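# Shared helpers: allele counting with hemizygous males, covariate design
# construction, and genomic-inflation summaries.

#' Minor allele counts and frequencies with hemizygous handling
#'
#' Computes per-group minor allele counts and frequencies for one variant.
#' Diploid samples contribute two alleles to the denominator, hemizygous
#' males on chromosome X contribute one; missing genotypes are excluded.
#'
#' @param g integer dosage vector (`NA` missing).
#' @param hemi logical vector flagging hemizygous samples.
#' @return list with `mac`, `n_alleles`, `freq`.
#' @export
allele_freq <- function(g, hemi = rep(FALSE, length(g))) {
  ok <- !is.na(g)
  mac <- sum(g[ok])
  n_alleles <- 2L * sum(ok & !hemi) + sum(ok & hemi)
  list(mac = mac, n_alleles = n_alleles,
       freq = if (n_alleles > 0) mac / n_alleles else NA_real_)
}

.hemi_flags <- function(samples, variants) {
  male <- samples$sex == 1L
  lapply(seq_len(nrow(variants)), function(v)
    if (variants$chrom[v] == "X") male else rep(FALSE, nrow(samples)))
}

#' Build the standard covariate matrix
#'
#' Sex, the first `n_pcs` principal components and the per-sample rare
#' synonymous count, as used by the association models.
#'
#' @param samples sample table with `sex`, `PC1..`, `syn_count`.
#' @param n_pcs number of PCs to include.
#' @param syn_count optional replacement synonymous-count vector (burden
#'   tests substitute the strategy-matched qualifying synonymous count).
#' @return numeric covariate matrix (no intercept).
#' @export
covariate_matrix <- function(samples, n_pcs = 10, syn_count = NULL) {
  pcs <- as.matrix(samples[, paste0("PC", seq_len(n_pcs)), drop = FALSE])
  if (is.null(syn_count)) syn_count <- samples$syn_count
  cbind(sex = as.numeric(samples$sex == 1L), pcs, syn_count = syn_count)
}

#' Genomic inflation factor rescaled to 1,000 cases and controls
#'
#' \eqn{\lambda} is the median association chi-square over its null median
#' (0.4549); \eqn{\lambda_{1000} = 1 + (\lambda - 1)(1/n_{cases} +
#' 1/n_{controls}) / (2/1000)} expresses it for an equivalent study of
#' 1,000 cases and 1,000 controls, making inflation comparable across
#' study sizes.
#'
#' @param pvals association p-values.
#' @param n_cases,n_controls study sample sizes.
#' @return list with `lambda` and `lambda_1000`.
#' @export
genomic_inflation <- function(pvals, n_cases, n_controls) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0L) stop("no p-values supplied")
  if (length(pvals) < 100L)
    warning("fewer than 100 p-values; inflation estimate is unstable")
  lambda <- median(qchisq(pvals, df = 1, lower.tail = FALSE)) /
    qchisq(0.5, df = 1, lower.tail = FALSE)
  l1000 <- 1 + (lambda - 1) * (1 / n_cases + 1 / n_controls) / (2 / 1000)
  list(lambda = lambda, lambda_1000 = l1000)
}

#' Bonferroni significance threshold
#'
#' @param n_tests number of tests performed.
#' @param alpha family-wise error rate.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(272925)   # exome-wide single-variant threshold
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}
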