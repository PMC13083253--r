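# Synthetic case-control exome cohorts with known ground truth.
#
# The generator emulates the design of a large unbalanced multi-cohort
# exome study: a heavy-tailed rare-variant MAF spectrum, impact-class
# labels, log-additive implanted risk variants, structured covariates
# (PCs with cohort shifts, sex, per-sample synonymous background),
# duplicate/related samples, and genotype-linked onset and survival
# phenotypes. Every downstream stage of the pipeline is testable against
# the recorded truth table.

.run_seeded <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration for synthetic exome cohorts
#'
#' Builds a validated configuration object for [simulate_cohort()]. Defaults
#' describe a modest unbalanced case-control design (1:10) over three
#' cohorts in two sequencing-technology supercohorts, ~100 genes with a
#' log-uniform MAF spectrum on (2e-5, 0.05], and no implanted effects.
#'
#' @param n_cases,n_controls target numbers of cases and controls. Status is
#'   drawn from the logistic liability model, so realized counts are
#'   binomial around these targets.
#' @param cohort_spec data frame with columns `cohort`, `supercohort`,
#'   `technology` ("WGS"/"WXS") and `fraction` (must sum to 1).
#' @param n_genes number of simulated genes.
#' @param variants_per_gene list with `mean`: gene variant counts are
#'   `1 + Poisson(mean)`.
#' @param maf_spectrum list with `min`, `max`: minor allele frequencies are
#'   drawn log-uniformly on (min, max], a heavy-tailed spectrum dominated by
#'   very rare variants.
#' @param impact_probs named probabilities for impact classes
#'   HIGH/MODERATE/SYNONYMOUS/OTHER.
#' @param effect_spec `NULL` or data frame of implanted effects with columns
#'   `gene`, `maf`, `or` (per-allele odds ratio), `impact`, and optionally
#'   `n_variants` (default 1), `onset_shift` (years per allele, cases) and
#'   `log_hr` (log hazard ratio per allele).
#' @param relatedness_spec list with `n_duplicate`, `n_second_degree`
#'   pair counts and `duplicate_discordance` (per-genotype discordance rate
#'   injected into the duplicate copy).
#' @param covariate_spec list: `n_pcs`, `sex_ratio` (fraction male),
#'   `pc_cohort_shift` (cohort mean shift on PC1/PC2), `syn_mean`
#'   (per-cohort Poisson mean of the exome-wide synonymous background,
#'   recycled), `sex_beta` and `pc1_beta` (liability covariate effects).
#' @param phenotype_spec list: `onset_mean`, `onset_sd` (years),
#'   `surv_median` (months, baseline), `censor_window` (months, uniform
#'   censoring).
#' @param indel_frac fraction of variants simulated as INDELs.
#' @param indel_long_frac fraction of INDELs given lengths > 50 bp (quality
#'   control positive controls).
#' @param chrx_frac probability that a gene is placed on chromosome X
#'   (male genotypes there are hemizygous, coded 0/1).
#' @param missing_rate baseline genotype missingness rate.
#' @param seed integer seed; all generator output is a pure function of the
#'   configuration including this seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 2000, n_controls = 20000,
                       cohort_spec = data.frame(
                         cohort = c("MINE", "UKB", "MISC"),
                         supercohort = c("WGS", "WXS_UKB", "WXS_OTH"),
                         technology = c("WGS", "WXS", "WXS"),
                         fraction = c(0.4, 0.4, 0.2)),
                       n_genes = 100,
                       variants_per_gene = list(mean = 4),
                       maf_spectrum = list(min = 2e-5, max = 0.05),
                       impact_probs = c(HIGH = 0.10, MODERATE = 0.45,
                                        SYNONYMOUS = 0.35, OTHER = 0.10),
                       effect_spec = NULL,
                       relatedness_spec = list(n_duplicate = 0,
                                               n_second_degree = 0,
                                               duplicate_discordance = 0),
                       covariate_spec = list(n_pcs = 10, sex_ratio = 0.5,
                                             pc_cohort_shift = 0.5,
                                             syn_mean = c(35, 40, 45),
                                             sex_beta = 0.1, pc1_beta = 0.1),
                       phenotype_spec = list(onset_mean = 65, onset_sd = 10,
                                             surv_median = 30,
                                             censor_window = c(12, 120)),
                       indel_frac = 0.1, indel_long_frac = 0,
                       chrx_frac = 0, missing_rate = 0, seed = 1L) {
  stopifnot(n_cases >= 0, n_controls >= 0, n_cases + n_controls > 0,
            n_genes >= 1, variants_per_gene$mean >= 0,
            maf_spectrum$min > 0, maf_spectrum$max <= 0.05,
            maf_spectrum$min <= maf_spectrum$max,
            indel_frac >= 0, indel_frac <= 1,
            chrx_frac >= 0, chrx_frac <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (abs(sum(cohort_spec$fraction) - 1) > 1e-9)
    stop("cohort fractions must sum to 1")
  if (!is.null(effect_spec)) {
    effect_spec <- as.data.frame(effect_spec)
    if (is.null(effect_spec$n_variants)) effect_spec$n_variants <- 1L
    if (is.null(effect_spec$onset_shift)) effect_spec$onset_shift <- 0
    if (is.null(effect_spec$log_hr)) effect_spec$log_hr <- 0
    if (any(effect_spec$or <= 0)) stop("every effect odds ratio must be > 0")
    if (any(effect_spec$maf <= 0 | effect_spec$maf > 0.05))
      stop("effect MAFs must lie in (0, 0.05]")
  }
  cfg <- list(n_cases = n_cases, n_controls = n_controls,
              cohort_spec = cohort_spec, n_genes = n_genes,
              variants_per_gene = variants_per_gene,
              maf_spectrum = maf_spectrum, impact_probs = impact_probs,
              effect_spec = effect_spec,
              relatedness_spec = relatedness_spec,
              covariate_spec = covariate_spec,
              phenotype_spec = phenotype_spec,
              indel_frac = indel_frac, indel_long_frac = indel_long_frac,
              chrx_frac = chrx_frac, missing_rate = missing_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

.draw_alleles <- function(vtype, vlen) {
  bases <- c("A", "C", "G", "T")
  n <- length(vtype)
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  indel <- vtype == "INDEL"
  if (any(indel)) {
    pad <- vapply(vlen[indel], function(L)
      paste(sample(bases, L, replace = TRUE), collapse = ""), "")
    alt[indel] <- ref[indel]
    ref[indel] <- paste0(ref[indel], pad)
  }
  list(ref = ref, alt = unname(alt))
}

#' Simulate a synthetic case-control exome cohort
#'
#' Generates genotypes, sample metadata, variant annotations, functional
#' units and a ground-truth effect table from a [sim_config()]. Disease
#' status is drawn from a logistic model whose linear predictor sums
#' log(OR) times dosage over implanted effect variants plus covariate
#' effects; all other variants are independent of status. Genotypes follow
#' Hardy-Weinberg sampling (two independent Bernoulli alleles; hemizygous
#' males on chromosome X carry a single allele, coded 0/1). Case onset age
#' and right-censored survival are linked to effect dosages through the
#' per-effect `onset_shift` and `log_hr` fields.
#'
#' @param config a [sim_config()] object.
#' @return object of class `synthetic_cohort`: list with `genotypes`
#'   (samples x variants integer dosage matrix, `NA` = missing), `samples`,
#'   `variants`, `gene_models`, `units` (gene units, random genesets, and a
#'   CDS-space domain table), `truth` (implanted effects and, after
#'   [inject_batch_artifacts()], batch artifacts), `relations` (duplicate /
#'   second-degree pairs) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .run_seeded(config$seed, {
    cs <- config$cohort_spec
    cov <- config$covariate_spec
    N <- config$n_cases + config$n_controls
    sample_id <- sprintf("S%06d", seq_len(N))

    sex <- sample(c(1L, 2L), N, replace = TRUE,
                  prob = c(cov$sex_ratio, 1 - cov$sex_ratio))
    cohort_idx <- sample.int(nrow(cs), N, replace = TRUE, prob = cs$fraction)
    cohort <- cs$cohort[cohort_idx]
    supercohort <- cs$supercohort[cohort_idx]
    technology <- cs$technology[cohort_idx]

    n_pcs <- cov$n_pcs
    pcs <- matrix(rnorm(N * n_pcs), N, n_pcs,
                  dimnames = list(NULL, paste0("PC", seq_len(n_pcs))))
    shift <- (cohort_idx - mean(seq_len(nrow(cs)))) * cov$pc_cohort_shift
    pcs[, 1] <- pcs[, 1] + shift
    if (n_pcs >= 2) pcs[, 2] <- pcs[, 2] - shift

    # -- variant panel ----------------------------------------------------
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    n_per_gene <- 1L + rpois(config$n_genes, config$variants_per_gene$mean)
    gene_chrom <- ifelse(runif(config$n_genes) < config$chrx_frac, "X",
                         as.character(sample(1:22, config$n_genes, TRUE)))
    cds_len <- 300L * sample(2:8, config$n_genes, replace = TRUE)
    gene_of <- rep(genes, n_per_gene)
    chrom <- rep(gene_chrom, n_per_gene)
    V0 <- length(gene_of)
    pos <- unlist(lapply(seq_len(config$n_genes), function(g)
      sort(sample.int(50000L, n_per_gene[g])) + g * 1000000L),
      use.names = FALSE)
    ms <- config$maf_spectrum
    maf <- ms$min * (ms$max / ms$min)^runif(V0)
    impact <- sample(names(config$impact_probs), V0, replace = TRUE,
                     prob = config$impact_probs)
    vtype <- ifelse(runif(V0) < config$indel_frac, "INDEL", "SNV")
    vlen <- ifelse(vtype == "SNV", 1L, 1L + rgeom(V0, 0.25))
    long <- vtype == "INDEL" & runif(V0) < config$indel_long_frac
    vlen[long] <- sample(51:80, sum(long), replace = TRUE)
    cds_pos <- vapply(match(gene_of, genes), function(g)
      sample.int(cds_len[g], 1L), 1L)
    or_allele <- rep(1, V0)
    onset_shift <- rep(0, V0)
    log_hr <- rep(0, V0)
    variant_id <- paste0("V", formatC(seq_len(V0), width = 5, flag = "0"))

    # implant effect variants
    truth_rows <- NULL
    es <- config$effect_spec
    if (!is.null(es) && nrow(es)) {
      for (i in seq_len(nrow(es))) {
        g <- es$gene[i]
        if (!g %in% genes) stop("effect gene not simulated: ", g)
        for (j in seq_len(es$n_variants[i])) {
          vid <- sprintf("%s_EFF%d_%d", g, i, j)
          if (round(2 * N * es$maf[i]) < 1)
            stop("infeasible effect variant ", vid,
                 ": requested MAF ", es$maf[i],
                 " implies a minor allele count below 1 in ", N, " samples")
          gi <- match(g, genes)
          variant_id <- c(variant_id, vid)
          gene_of <- c(gene_of, g)
          chrom <- c(chrom, gene_chrom[gi])
          pos <- c(pos, gi * 1000000L + 60000L + i * 100L + j)
          maf <- c(maf, es$maf[i])
          impact <- c(impact, es$impact[i])
          vtype <- c(vtype, "SNV")
          vlen <- c(vlen, 1L)
          cds_pos <- c(cds_pos, sample.int(cds_len[gi], 1L))
          or_allele <- c(or_allele, es$or[i])
          onset_shift <- c(onset_shift, es$onset_shift[i])
          log_hr <- c(log_hr, es$log_hr[i])
          truth_rows <- rbind(truth_rows, data.frame(
            variant_id = vid, gene = g, maf = es$maf[i], or = es$or[i],
            impact = es$impact[i], onset_shift = es$onset_shift[i],
            log_hr = es$log_hr[i]))
        }
      }
    }
    V <- length(variant_id)
    alle <- .draw_alleles(vtype, vlen)

    # -- genotypes (HWE; hemizygous males on chrX) ------------------------
    male <- sex == 1L
    G <- matrix(0L, N, V, dimnames = list(sample_id, variant_id))
    for (v in seq_len(V)) {
      if (chrom[v] == "X") {
        g <- integer(N)
        g[male] <- rbinom(sum(male), 1L, maf[v])
        g[!male] <- rbinom(sum(!male), 2L, maf[v])
      } else {
        g <- rbinom(N, 2L, maf[v])
      }
      G[, v] <- g
    }

    # -- status from the logistic liability -------------------------------
    eta <- qlogis(config$n_cases / N) +
      cov$sex_beta * (sex == 1L) + cov$pc1_beta * pcs[, 1]
    eff <- which(or_allele != 1)
    if (length(eff))
      eta <- eta + as.numeric(G[, eff, drop = FALSE] %*% log(or_allele[eff]))
    status <- rbinom(N, 1L, plogis(eta))

    # -- synonymous background count --------------------------------------
    syn_mean <- rep_len(cov$syn_mean, nrow(cs))
    syn_panel <- if (any(impact == "SYNONYMOUS"))
      rowSums(G[, impact == "SYNONYMOUS", drop = FALSE]) else 0L
    syn_count <- syn_panel + rpois(N, syn_mean[cohort_idx])

    # -- onset and survival (cases only) ----------------------------------
    ph <- config$phenotype_spec
    onset <- rnorm(N, ph$onset_mean, ph$onset_sd)
    haz <- rep(log(2) / ph$surv_median, N)
    if (length(eff)) {
      onset <- onset + as.numeric(G[, eff, drop = FALSE] %*% onset_shift[eff])
      haz <- haz * exp(as.numeric(G[, eff, drop = FALSE] %*% log_hr[eff]))
    }
    onset <- pmax(onset, 18)
    t_ev <- rexp(N, haz)
    t_cn <- runif(N, ph$censor_window[1], ph$censor_window[2])
    surv_months <- pmin(t_ev, t_cn)
    surv_event <- as.integer(t_ev <= t_cn)
    onset[status == 0L] <- NA
    surv_months[status == 0L] <- NA
    surv_event[status == 0L] <- NA_integer_

    # -- baseline missingness ---------------------------------------------
    if (config$missing_rate > 0 && V > 0)
      G[matrix(runif(N * V) < config$missing_rate, N, V)] <- NA_integer_

    # -- related / duplicate samples --------------------------------------
    rs <- config$relatedness_spec
    relations <- data.frame(sample_a = character(), sample_b = character(),
                            relation = character())
    n_pairs <- rs$n_duplicate + rs$n_second_degree
    if (n_pairs > 0) {
      if (2 * n_pairs > N) stop("not enough samples for requested related pairs")
      pick <- matrix(sample(sample_id, 2 * n_pairs), ncol = 2)
      k <- 0L
      if (rs$n_duplicate > 0) {
        for (i in seq_len(rs$n_duplicate)) {
          k <- k + 1L
          a <- pick[k, 1]; b <- pick[k, 2]
          gb <- G[a, ]
          if (isTRUE(rs$duplicate_discordance > 0)) {
            flip <- runif(V) < rs$duplicate_discordance
            gb[flip] <- ifelse(is.na(gb[flip]) | gb[flip] > 0L, 0L, 1L)
          }
          G[b, ] <- gb
          relations <- rbind(relations, data.frame(
            sample_a = a, sample_b = b, relation = "duplicate"))
        }
      }
      if (rs$n_second_degree > 0) {
        for (i in seq_len(rs$n_second_degree)) {
          k <- k + 1L
          relations <- rbind(relations, data.frame(
            sample_a = pick[k, 1], sample_b = pick[k, 2],
            relation = "second_degree"))
        }
      }
    }

    samples <- data.frame(sample_id = sample_id,
                          phenotype = status + 1L, sex = sex,
                          cohort = cohort, supercohort = supercohort,
                          technology = technology,
                          pcs, syn_count = syn_count,
                          onset_age = onset, surv_months = surv_months,
                          surv_event = surv_event)
    variants <- data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
                           ref = alle$ref, alt = alle$alt, gene = gene_of,
                           impact = impact, vtype = vtype, length = vlen,
                           cds_pos = cds_pos, maf_target = maf)
    variants <- cbind(variants,
                      supercohort_call_rates(G, samples$supercohort))
    gene_models <- data.frame(gene = genes,
                              transcript = paste0(genes, "_T1"),
                              cds_len = cds_len)

    # functional units: one per gene, a few random genesets, CDS domains
    gene_units <- lapply(genes, function(g) functional_unit(
      g, "gene", variants$variant_id[variants$gene == g], g))
    names(gene_units) <- genes
    n_sets <- min(8L, max(1L, config$n_genes %/% 10L))
    set_lo <- min(5L, config$n_genes)
    set_hi <- min(30L, config$n_genes)
    genesets <- lapply(seq_len(n_sets), function(i)
      sample(genes, sample(set_lo:set_hi, 1L)))
    names(genesets) <- sprintf("SET%02d", seq_len(n_sets))
    dom_genes <- which(runif(config$n_genes) < 0.3)
    domains <- if (length(dom_genes)) do.call(rbind, lapply(dom_genes, function(g) {
      w <- round(cds_len[g] * runif(1, 0.3, 0.6))
      s <- sample.int(cds_len[g] - w, 1L)
      data.frame(transcript = paste0(genes[g], "_T1"),
                 domain_id = paste0(genes[g], "_D1"),
                 cds_start = s, cds_end = s + w - 1L)
    })) else data.frame(transcript = character(), domain_id = character(),
                        cds_start = integer(), cds_end = integer())

    out <- list(genotypes = G, samples = samples, variants = variants,
                gene_models = gene_models,
                units = list(genes = gene_units, genesets = genesets,
                             domains = domains),
                truth = list(effects = truth_rows,
                             batch = NULL),
                relations = relations, config = config)
    class(out) <- "synthetic_cohort"
    out
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic exome cohort:", nrow(x$samples), "samples (",
      sum(x$samples$phenotype == 2L), "cases ),",
      nrow(x$variants), "variants in", nrow(x$gene_models), "genes\n")
  if (!is.null(x$truth$effects))
    cat("Implanted effects:", nrow(x$truth$effects), "variants\n")
  if (!is.null(x$truth$batch))
    cat("Batch artifacts:", nrow(x$truth$batch), "variant-cohort pairs\n")
  invisible(x)
}

#' Inject cohort-specific batch artifacts
#'
#' Gives selected variants cohort-specific missingness and genotype error
#' (spurious heterozygous calls), providing positive controls for the
#' control-control batch-effect scan and the per-supercohort call-rate
#' filter. Affected variants are recorded in `truth$batch`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param batch_spec data frame with columns `cohort`, `n_variants`,
#'   `missingness` (per-genotype missing rate in that cohort) and
#'   `error_rate` (rate at which non-carrier genotypes in that cohort are
#'   flipped to heterozygous).
#' @param seed RNG seed for variant selection and artifact placement
#'   (defaults to the cohort seed plus one).
#' @return the modified cohort.
#' @export
inject_batch_artifacts <- function(cohort, batch_spec,
                                   seed = cohort$config$seed + 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  batch_spec <- as.data.frame(batch_spec)
  bad <- setdiff(batch_spec$cohort, cohort$samples$cohort)
  if (length(bad)) stop("unknown cohort id: ", paste(bad, collapse = ", "))
  .run_seeded(seed, {
    G <- cohort$genotypes
    rec <- NULL
    for (i in seq_len(nrow(batch_spec))) {
      rows <- which(cohort$samples$cohort == batch_spec$cohort[i])
      vsel <- sample(colnames(G), min(batch_spec$n_variants[i], ncol(G)))
      for (v in vsel) {
        g <- G[rows, v]
        if (batch_spec$error_rate[i] > 0) {
          flip <- !is.na(g) & g == 0L &
            runif(length(g)) < batch_spec$error_rate[i]
          g[flip] <- 1L
        }
        if (batch_spec$missingness[i] > 0)
          g[runif(length(g)) < batch_spec$missingness[i]] <- NA_integer_
        G[rows, v] <- g
      }
      rec <- rbind(rec, data.frame(
        variant_id = vsel, cohort = batch_spec$cohort[i],
        missingness = batch_spec$missingness[i],
        error_rate = batch_spec$error_rate[i]))
    }
    cohort$genotypes <- G
    cohort$truth$batch <- rbind(cohort$truth$batch, rec)
    sc_cr <- supercohort_call_rates(G, cohort$samples$supercohort)
    cohort$variants[colnames(sc_cr)] <- sc_cr
    cohort
  })
}

#' Per-supercohort variant call rates
#'
#' @param G samples x variants dosage matrix with `NA` for missing.
#' @param supercohort per-sample supercohort labels.
#' @return data frame with one `cr_<supercohort>` column per supercohort.
#' @export
supercohort_call_rates <- function(G, supercohort) {
  scs <- sort(unique(supercohort))
  out <- lapply(scs, function(sc) {
    rows <- supercohort == sc
    if (!any(rows)) stop("supercohort with zero samples: ", sc)
    colMeans(!is.na(G[rows, , drop = FALSE]))
  })
  names(out) <- paste0("cr_", scs)
  as.data.frame(out, optional = TRUE,
                row.names = seq_len(ncol(G)))
}

#' Construct a functional aggregation unit
#'
#' @param unit_id unit identifier.
#' @param unit_kind one of "gene", "domain", "geneset".
#' @param members character vector of member variant ids (nonempty).
#' @param genes member gene ids (genesets).
#' @return object of class `functional_unit`.
#' @export
functional_unit <- function(unit_id, unit_kind = c("gene", "domain", "geneset"),
                            members, genes = NULL) {
  unit_kind <- match.arg(unit_kind)
  if (length(members) == 0L)
    stop("functional unit ", unit_id, " has no member variants")
  structure(list(unit_id = unit_id, unit_kind = unit_kind,
                 members = unique(members), genes = unique(genes)),
            class = "functional_unit")
}
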