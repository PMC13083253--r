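# Sample-level quality control: per-sample exome metrics, threshold
# filtering with per-sample exclusion reasons, and greedy unrelated-set
# selection over the relation graph.

.is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Per-sample quality-control metrics
#'
#' Computes, over non-missing genotypes: call rate, counts of SNVs, INDELs
#' and singletons carried, the Ti/Tv ratio of carried SNVs, the INDEL/SNV
#' ratio, and the inbreeding coefficient `F = 1 - observed het / expected
#' het` with expected heterozygosity from pooled allele frequencies over
#' the metric variant set (autosomal variants; chromosome X is excluded so
#' hemizygous males do not bias F).
#'
#' @param G samples x variants dosage matrix.
#' @param variants variant table with `chrom`, `ref`, `alt`, `vtype`.
#' @return data frame of per-sample metrics; samples with no callable
#'   genotypes (or zero expected heterozygosity) get `NA` metrics rather
#'   than failing.
#' @export
sample_metrics <- function(G, variants) {
  stopifnot(ncol(G) == nrow(variants))
  auto <- variants$chrom != "X"
  Ga <- G[, auto, drop = FALSE]
  va <- variants[auto, , drop = FALSE]
  nonmiss <- !is.na(Ga)
  call_rate <- rowMeans(!is.na(G))

  carried <- !is.na(Ga) & Ga >= 1L
  snv <- va$vtype == "SNV"
  n_snv <- rowSums(carried[, snv, drop = FALSE])
  n_indel <- rowSums(carried[, !snv, drop = FALSE])
  carriers_per_variant <- colSums(carried)
  singleton_v <- carriers_per_variant == 1L
  n_singleton <- rowSums(carried[, singleton_v, drop = FALSE])

  ti <- snv & .is_transition(va$ref, va$alt)
  tv <- snv & !.is_transition(va$ref, va$alt)
  n_ti <- rowSums(carried[, ti, drop = FALSE])
  n_tv <- rowSums(carried[, tv, drop = FALSE])
  titv <- ifelse(n_tv > 0, n_ti / n_tv, NA_real_)
  indel_snv_ratio <- ifelse(n_snv > 0, n_indel / n_snv, NA_real_)

  p <- colSums(Ga, na.rm = TRUE) / (2 * pmax(colSums(nonmiss), 1L))
  exp_het_v <- 2 * p * (1 - p)
  obs_het <- rowSums(!is.na(Ga) & Ga == 1L)
  exp_het <- as.numeric(nonmiss %*% exp_het_v)
  het_f <- ifelse(exp_het > 0, 1 - obs_het / exp_het, NA_real_)
  het_f[rowSums(nonmiss) == 0L] <- NA_real_

  data.frame(sample_id = rownames(G), call_rate = call_rate,
             het_f = het_f, n_snv = n_snv, n_indel = n_indel,
             n_singleton = n_singleton, titv = titv,
             indel_snv_ratio = indel_snv_ratio)
}

#' Filter samples on QC metrics
#'
#' Applies the call-rate and heterozygosity filters plus robust z-score
#' bands on the exome-wide count metrics. Every excluded sample lists all
#' violated rules. Optional sex-discordance exclusion compares a reported
#' and an externally inferred sex column when both are present in
#' `metrics`.
#'
#' @param metrics [sample_metrics()] output (optionally with `sex` and
#'   `inferred_sex` columns).
#' @param thresholds list: `call_rate_min` (default 0.9), `f_range`
#'   (default c(-0.1, 0.1)), `z_max` (robust z bound for n_snv, n_indel,
#'   n_singleton, titv, indel_snv_ratio; default Inf, i.e. off).
#' @return list with `kept` sample ids and `exclusions` data frame
#'   (`sample_id`, `reasons`).
#' @export
filter_samples <- function(metrics,
                           thresholds = list(call_rate_min = 0.9,
                                             f_range = c(-0.1, 0.1),
                                             z_max = Inf)) {
  th <- utils::modifyList(list(call_rate_min = 0.9, f_range = c(-0.1, 0.1),
                               z_max = Inf), thresholds)
  reasons <- vector("list", nrow(metrics))
  add <- function(idx, msg) for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], msg)

  add(metrics$call_rate < th$call_rate_min,
      sprintf("call_rate<%g", th$call_rate_min))
  add(!is.na(metrics$het_f) &
        (metrics$het_f < th$f_range[1] | metrics$het_f > th$f_range[2]),
      sprintf("F outside [%g,%g]", th$f_range[1], th$f_range[2]))
  if (is.finite(th$z_max)) {
    for (m in c("n_snv", "n_indel", "n_singleton", "titv", "indel_snv_ratio")) {
      v <- metrics[[m]]
      s <- mad(v, na.rm = TRUE)
      if (!is.na(s) && s > 0) {
        z <- (v - median(v, na.rm = TRUE)) / s
        add(!is.na(z) & abs(z) > th$z_max, sprintf("%s |z|>%g", m, th$z_max))
      }
    }
  }
  if (!is.null(metrics$sex) && !is.null(metrics$inferred_sex))
    add(!is.na(metrics$inferred_sex) & metrics$sex != metrics$inferred_sex,
        "discordant sex")

  excluded <- lengths(reasons) > 0L
  list(kept = metrics$sample_id[!excluded],
       exclusions = data.frame(
         sample_id = metrics$sample_id[excluded],
         reasons = vapply(reasons[excluded], paste, "", collapse = ";")))
}

#' Greedy selection of an unrelated sample set
#'
#' Two-phase pruning of the relation graph (duplicates and relatives up to
#' the second degree): first all samples with five or more relations are
#' removed; then the sample with the highest remaining relation count is
#' removed iteratively until no related pairs remain. Ties are resolved by
#' removing, in order, controls before cases, WXS before WGS samples, then
#' the lexicographically smallest id — i.e. cases and WGS samples are
#' preferentially retained.
#'
#' @param nodes data frame with `sample_id`, `phenotype` (1 control /
#'   2 case) and `technology` ("WGS"/"WXS").
#' @param edges data frame of related pairs with columns `sample_a`,
#'   `sample_b` (undirected; self-pairs are rejected).
#' @return character vector of retained sample ids (an edge-free set).
#' @export
select_unrelated <- function(nodes, edges) {
  if (any(edges$sample_a == edges$sample_b)) stop("self-relations not allowed")
  ids <- nodes$sample_id
  a <- match(edges$sample_a, ids)
  b <- match(edges$sample_b, ids)
  if (anyNA(a) || anyNA(b)) stop("edge references unknown sample id")
  alive <- rep(TRUE, length(ids))
  e_alive <- rep(TRUE, length(a))
  degree <- function() {
    d <- integer(length(ids))
    if (any(e_alive)) {
      t1 <- table(a[e_alive]); t2 <- table(b[e_alive])
      d[as.integer(names(t1))] <- d[as.integer(names(t1))] + as.integer(t1)
      d[as.integer(names(t2))] <- d[as.integer(names(t2))] + as.integer(t2)
    }
    d
  }
  drop_node <- function(i) {
    alive[i] <<- FALSE
    e_alive[a == i | b == i] <<- FALSE
  }

  # phase 1: remove all samples with >= 5 relations (degrees on input graph)
  d0 <- degree()
  for (i in which(d0 >= 5L)) drop_node(i)

  # phase 2: iterative max-degree removal with tie-breaking
  repeat {
    d <- degree()
    if (max(d) == 0L) break
    cand <- which(d == max(d))
    if (length(cand) > 1L) {
      pref <- order(nodes$phenotype[cand],            # controls (1) first
                    nodes$technology[cand] == "WGS",  # WXS first
                    ids[cand])                        # smallest id first
      cand <- cand[pref[1L]]
    }
    drop_node(cand[1L])
  }
  ids[alive]
}
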