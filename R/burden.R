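# Ultrarare-variant burden testing over genes, protein domains and
# genesets. A 2x2 grid of filtering strategies (carrier frequency x impact
# severity) feeds per-unit Firth penalized-LRT tests whose p-values are
# combined with the Cauchy (ACAT) omnibus statistic.

#' The four URV filtering strategies
#'
#' The grid crosses a carrier-frequency rule (`ultrarare`: five or fewer
#' carriers; `singleton`: exactly one carrier) with an impact rule
#' (`high`: HIGH only; `high_moderate`: HIGH plus MODERATE).
#'
#' @return data frame with columns `strategy`, `frequency`, `impact`.
#' @export
strategy_grid <- function() {
  g <- expand.grid(frequency = c("ultrarare", "singleton"),
                   impact = c("high", "high_moderate"),
                   stringsAsFactors = FALSE)
  g$strategy <- paste(g$impact, g$frequency, sep = "/")
  g[, c("strategy", "frequency", "impact")]
}

.carrier_counts <- function(G) colSums(!is.na(G) & G >= 1L)

#' Variants qualifying under a filtering strategy
#'
#' A carrier is a sample with at least one minor allele (missing genotypes
#' never count as carriage). The frequency rule bounds the carrier count;
#' the impact rule restricts annotation classes.
#'
#' @param G samples x variants dosage matrix.
#' @param variants variant table with `variant_id` and `impact`.
#' @param frequency `"ultrarare"` (<= `max_carriers`) or `"singleton"`
#'   (exactly one carrier).
#' @param impact `"high"` or `"high_moderate"`.
#' @param max_carriers carrier bound defining "ultrarare" (default 5).
#' @return character vector of qualifying variant ids.
#' @export
qualify_variants <- function(G, variants,
                             frequency = c("ultrarare", "singleton"),
                             impact = c("high_moderate", "high"),
                             max_carriers = 5L) {
  frequency <- match.arg(frequency)
  impact <- match.arg(impact)
  carriers <- .carrier_counts(G)
  freq_ok <- if (frequency == "singleton") carriers == 1L
             else carriers >= 1L & carriers <= max_carriers
  classes <- if (impact == "high") "HIGH" else c("HIGH", "MODERATE")
  variants$variant_id[freq_ok & variants$impact %in% classes]
}

#' Per-sample burden score for a functional unit
#'
#' Sum of minor-allele dosages over the unit's qualifying member variants;
#' missing genotypes contribute zero.
#'
#' @param G samples x variants dosage matrix.
#' @param unit a [functional_unit()].
#' @param qualifying qualifying variant ids (from [qualify_variants()]).
#' @return numeric per-sample score vector; attribute `status` is
#'   `"no qualifying variants"` when the intersection is empty.
#' @export
burden_score <- function(G, unit, qualifying) {
  m <- intersect(unit$members, qualifying)
  if (length(m) == 0L) {
    s <- numeric(nrow(G))
    attr(s, "status") <- "no qualifying variants"
    return(s)
  }
  rowSums(G[, m, drop = FALSE], na.rm = TRUE)
}

.qualifying_syn_count <- function(G, variants, frequency, max_carriers = 5L) {
  carriers <- .carrier_counts(G)
  freq_ok <- if (frequency == "singleton") carriers == 1L
             else carriers >= 1L & carriers <= max_carriers
  syn <- freq_ok & variants$impact == "SYNONYMOUS"
  if (!any(syn)) return(numeric(nrow(G)))
  rowSums(G[, syn, drop = FALSE], na.rm = TRUE)
}

#' Burden scan over functional units
#'
#' For every unit and filtering strategy, tests the per-sample burden score
#' against case status with the Firth penalized LRT, adjusting for sex,
#' the leading PCs and the qualifying synonymous count (synonymous
#' variants re-qualified under the same frequency rule, so the covariate
#' matches the exposure's frequency stratum). A unit-strategy test is
#' retained only with at least `min_carriers` carriers across the unit;
#' per unit, retained strategy p-values are combined with
#' [acat_combine()].
#'
#' @param G samples x variants dosage matrix.
#' @param samples sample table.
#' @param units list of [functional_unit()] objects.
#' @param variants variant table.
#' @param strategies subset of [strategy_grid()] rows (default all four).
#' @param min_carriers retention rule (default 10).
#' @param n_pcs PCs to adjust for.
#' @param max_carriers carrier bound defining "ultrarare".
#' @param vtype_filter optional `"SNV"`/`"INDEL"` restriction for
#'   sensitivity splits.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @return list with `results` (unit x strategy rows), `omnibus` (one row
#'   per unit: `p_acat`, `n_retained`) and `summary` (`n_units_tested`,
#'   `bonferroni`, `lambda_1000`).
#' @export
unit_scan <- function(G, samples, units, variants,
                      strategies = strategy_grid(), min_carriers = 10L,
                      n_pcs = 10, max_carriers = 5L, vtype_filter = NULL,
                      alpha = 0.05) {
  stopifnot(ncol(G) == nrow(variants), nrow(G) == nrow(samples))
  if (!is.null(vtype_filter)) {
    keep <- variants$vtype %in% vtype_filter
    G <- G[, keep, drop = FALSE]
    variants <- variants[keep, , drop = FALSE]
  }
  covars0 <- covariate_matrix(samples, n_pcs = n_pcs)
  ok <- complete.cases(covars0) & !is.na(samples$phenotype)
  y <- as.numeric(samples$phenotype == 2L)[ok]

  res <- NULL
  for (s in seq_len(nrow(strategies))) {
    qual <- qualify_variants(G, variants, strategies$frequency[s],
                             strategies$impact[s], max_carriers)
    syn_q <- .qualifying_syn_count(G, variants, strategies$frequency[s],
                                   max_carriers)
    covars <- covariate_matrix(samples, n_pcs = n_pcs, syn_count = syn_q)
    covars <- covars[ok, , drop = FALSE]
    X0 <- .validate_design(cbind(`(Intercept)` = 1, covars), y)
    warm <- unname(fit_firth(X0, y)$beta)
    for (u in units) {
      score <- burden_score(G, u, qual)[ok]
      carrier <- score > 0
      n_cc <- sum(carrier & y == 1)
      n_c0 <- sum(carrier & y == 0)
      retained <- (n_cc + n_c0) >= min_carriers
      row <- data.frame(unit_id = u$unit_id, unit_kind = u$unit_kind,
                        strategy = strategies$strategy[s],
                        n_case_carriers = n_cc, n_control_carriers = n_c0,
                        or_ = NA_real_, p = NA_real_, retained = retained,
                        status = if (!is.null(attr(score, "status")))
                          attr(score, "status") else "ok")
      if (retained) {
        X <- cbind(`(Intercept)` = 1, burden = score, covars)
        fit <- tryCatch(.firth_lrt_core(X, y, index = 2L,
                                        init = c(warm[1L], 0, warm[-1L])),
                        error = function(e) NULL)
        if (!is.null(fit)) {
          row$or_ <- exp(unname(fit$fit$beta[2L]))
          row$p <- fit$p
        } else {
          row$retained <- FALSE
          row$status <- "fit failed"
        }
      }
      res <- rbind(res, row)
    }
  }
  omnibus <- do.call(rbind, lapply(split(res, res$unit_id), function(d) {
    keep <- d$retained & !is.na(d$p)
    data.frame(unit_id = d$unit_id[1], unit_kind = d$unit_kind[1],
               n_retained = sum(keep),
               p_acat = if (any(keep)) acat_combine(d$p[keep]) else NA_real_)
  }))
  rownames(omnibus) <- NULL
  tested <- !is.na(omnibus$p_acat)
  lam <- if (sum(tested) >= 1L)
    suppressWarnings(genomic_inflation(omnibus$p_acat[tested],
                                       sum(y == 1), sum(y == 0))$lambda_1000)
  else NA_real_
  list(results = res, omnibus = omnibus,
       summary = list(n_units_tested = sum(tested),
                      bonferroni = if (any(tested))
                        bonferroni_threshold(sum(tested), alpha) else NA_real_,
                      lambda_1000 = lam))
}

#' Conditional burden test of one unit given another
#'
#' Tests unit A's burden with unit B's burden score included as an extra
#' covariate: the penalized LRT on A's score then measures A's
#' contribution beyond what B explains (e.g. a child geneset conditioned
#' on its parent term).
#'
#' @inheritParams unit_scan
#' @param unit_a,unit_b [functional_unit()] objects.
#' @param frequency,impact the filtering strategy to apply to both units.
#' @return list with `p`, `or_` for unit A's conditional effect.
#' @export
conditional_unit_test <- function(G, samples, unit_a, unit_b, variants,
                                  frequency = "ultrarare",
                                  impact = "high_moderate",
                                  n_pcs = 10, max_carriers = 5L) {
  qual <- qualify_variants(G, variants, frequency, impact, max_carriers)
  syn_q <- .qualifying_syn_count(G, variants, frequency, max_carriers)
  covars0 <- covariate_matrix(samples, n_pcs = n_pcs, syn_count = syn_q)
  ok <- complete.cases(covars0) & !is.na(samples$phenotype)
  y <- as.numeric(samples$phenotype == 2L)[ok]
  sa <- burden_score(G, unit_a, qual)[ok]
  sb <- burden_score(G, unit_b, qual)[ok]
  if (stats::sd(sa) > 0 && stats::sd(sb) > 0 &&
      abs(stats::cor(sa, sb)) > 1 - 1e-12)
    stop("units indistinguishable: burden scores are perfectly collinear")
  drop_b <- stats::sd(sb) == 0  # zero-carrier conditioning unit
  X <- if (drop_b)
    cbind(`(Intercept)` = 1, burden_a = sa, covars0[ok, , drop = FALSE])
  else
    cbind(`(Intercept)` = 1, burden_a = sa, burden_b = sb,
          covars0[ok, , drop = FALSE])
  fit <- penalized_lr_test(X, y, index = 2L)
  list(p = fit$p, or_ = exp(unname(fit$fit$beta[2L])))
}

#' Map a genomic position to CDS-relative coordinates
#'
#' Exonic positions map to their exact 1-based offset within the coding
#' sequence; positions up to `border_bp` outside a CDS border (intron or
#' UTR side) are attributed to that border; positions farther away return
#' `NA`. Minus-strand transcripts are numbered from their rightmost
#' genomic coordinate.
#'
#' @param transcript list with `exons` (data frame `start`, `end`, 1-based
#'   inclusive genomic CDS exon coordinates) and `strand` (`"+"`/`"-"`).
#' @param pos genomic position(s).
#' @param border_bp tolerance for near-border intronic/UTR positions
#'   (default 12).
#' @return integer CDS coordinate(s), `NA` where unmappable.
#' @export
map_to_cds <- function(transcript, pos, border_bp = 12L) {
  ex <- transcript$exons[order(transcript$exons$start), , drop = FALSE]
  if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
    stop("malformed transcript: overlapping exons")
  widths <- ex$end - ex$start + 1L
  cum <- cumsum(c(0L, widths[-length(widths)]))
  total <- sum(widths)
  minus <- identical(transcript$strand, "-")

  vapply(pos, function(p) {
    # snap near-border positions onto the closest border within range
    d_start <- ex$start - p   # >0: p left of exon
    d_end <- p - ex$end       # >0: p right of exon
    inside <- which(p >= ex$start & p <= ex$end)
    if (length(inside) == 0L) {
      cand <- c(d_start[d_start > 0], d_end[d_end > 0])
      if (length(cand) == 0L || min(cand) > border_bp) return(NA_integer_)
      if (min(d_start[d_start > 0], Inf) <= min(d_end[d_end > 0], Inf)) {
        i <- which(d_start == min(d_start[d_start > 0]))[1L]
        p <- ex$start[i]
      } else {
        i <- which(d_end == min(d_end[d_end > 0]))[1L]
        p <- ex$end[i]
      }
      inside <- i
    }
    i <- inside[1L]
    plus_coord <- cum[i] + (p - ex$start[i]) + 1L
    as.integer(if (minus) total - plus_coord + 1L else plus_coord)
  }, 1L)
}

#' Build protein-domain functional units
#'
#' One unit per (transcript, domain). Domains spanning more than
#' `max_span` of the transcript's CDS length are dropped (such "domains"
#' are indistinguishable from the whole gene); member variants are those
#' whose CDS coordinate falls inside the domain interval.
#'
#' @param domains data frame `transcript`, `domain_id`, `cds_start`,
#'   `cds_end` (1-based inclusive, CDS-relative).
#' @param gene_models data frame `gene`, `transcript`, `cds_len`.
#' @param variants variant table with `gene` and `cds_pos`.
#' @param max_span maximal domain width as a fraction of CDS length
#'   (default 0.9, strict).
#' @return list of [functional_unit()] objects (empty-member domains are
#'   skipped).
#' @export
build_domain_units <- function(domains, gene_models, variants,
                               max_span = 0.9) {
  units <- list()
  for (i in seq_len(nrow(domains))) {
    tr <- domains$transcript[i]
    gm <- gene_models[gene_models$transcript == tr, , drop = FALSE]
    if (nrow(gm) == 0L) stop("unknown transcript: ", tr)
    if (domains$cds_start[i] < 1L || domains$cds_end[i] > gm$cds_len ||
        domains$cds_start[i] > domains$cds_end[i])
      stop("domain ", domains$domain_id[i], " outside CDS bounds")
    width <- domains$cds_end[i] - domains$cds_start[i] + 1L
    if (width > max_span * gm$cds_len) next
    vs <- variants[variants$gene == gm$gene &
                     !is.na(variants$cds_pos) &
                     variants$cds_pos >= domains$cds_start[i] &
                     variants$cds_pos <= domains$cds_end[i], , drop = FALSE]
    if (nrow(vs) == 0L) next
    units[[length(units) + 1L]] <- functional_unit(
      paste(tr, domains$domain_id[i], sep = ":"), "domain",
      vs$variant_id, gm$gene)
  }
  units
}

#' Load genesets from a GMT file as functional units
#'
#' Sets are intersected with the genes present in the variant table before
#' the size filter; sets with fewer than `min_size` or more than
#' `max_size` genes are excluded.
#'
#' @param path GMT file path (or a named list of gene vectors).
#' @param variants variant table with `gene` and `variant_id`.
#' @param min_size,max_size inclusive size bounds (defaults 5 and 1000).
#' @return list of [functional_unit()] objects.
#' @export
load_genesets <- function(path, variants, min_size = 5L, max_size = 1000L) {
  sets <- if (is.character(path)) read_gmt(path) else path
  units <- list()
  for (nm in names(sets)) {
    genes <- intersect(unique(sets[[nm]]), unique(variants$gene))
    if (length(genes) < min_size || length(genes) > max_size) next
    members <- variants$variant_id[variants$gene %in% genes]
    if (length(members) == 0L) next
    units[[length(units) + 1L]] <- functional_unit(nm, "geneset",
                                                   members, genes)
  }
  units
}
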