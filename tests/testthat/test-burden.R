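# URV burden machinery: strategy qualification and nesting, score
# semantics, retention and ACAT omnibus, CDS mapping, domain and geneset
# unit construction, conditional tests, and the SNV/INDEL split.

burden_fixture <- function(seed = 30, n_cases = 120, n_controls = 600) {
  cfg <- sim_config(n_cases = n_cases, n_controls = n_controls,
                    n_genes = 20, seed = seed,
                    variants_per_gene = list(mean = 10),
                    maf_spectrum = list(min = 2e-4, max = 0.02))
  simulate_cohort(cfg)
}

test_that("strategy qualification enforces carrier and impact rules", {
  co <- burden_fixture()
  G <- co$genotypes; v <- co$variants
  carriers <- colSums(!is.na(G) & G >= 1L)
  q_ur <- qualify_variants(G, v, "ultrarare", "high_moderate")
  q_si <- qualify_variants(G, v, "singleton", "high_moderate")
  q_hi <- qualify_variants(G, v, "ultrarare", "high")
  # six or more carriers never qualify as ultrarare
  expect_true(all(carriers[match(q_ur, v$variant_id)] <= 5))
  expect_true(all(carriers[match(q_si, v$variant_id)] == 1))
  # nesting in both directions of the grid
  expect_true(all(q_si %in% q_ur))
  expect_true(all(q_hi %in% q_ur))
  expect_true(all(v$impact[match(q_hi, v$variant_id)] == "HIGH"))
  expect_false(any(v$impact[match(q_ur, v$variant_id)] %in%
                     c("SYNONYMOUS", "OTHER")))
  # a 6-carrier variant is excluded explicitly
  six <- v$variant_id[carriers == 6 & v$impact %in% c("HIGH", "MODERATE")]
  expect_false(any(six %in% q_ur))
})

test_that("burden scores equal the dense row-sum oracle", {
  co <- burden_fixture(31)
  g1 <- co$gene_models$gene[3]
  unit <- co$units$genes[[g1]]
  qual <- qualify_variants(co$genotypes, co$variants, "ultrarare",
                           "high_moderate")
  s <- burden_score(co$genotypes, unit, qual)
  m <- intersect(unit$members, qual)
  oracle <- apply(co$genotypes[, m, drop = FALSE], 1,
                  function(r) sum(r, na.rm = TRUE))
  expect_equal(unname(s), unname(oracle))
  # empty qualifying set flags the unit
  s0 <- burden_score(co$genotypes, unit, character(0))
  expect_equal(attr(s0, "status"), "no qualifying variants")
  expect_true(all(s0 == 0))
})

test_that("unit scan applies the ten-carrier retention rule and ACAT identity", {
  co <- burden_fixture(32)
  us <- unit_scan(co$genotypes, co$samples, co$units$genes, co$variants)
  res <- us$results; om <- us$omnibus
  # retention bookkeeping is carrier-count driven
  tot <- res$n_case_carriers + res$n_control_carriers
  expect_true(all(!res$retained[tot < 10]))
  expect_true(all(res$retained[tot >= 10 & res$status == "ok"]))
  not_ret <- om$unit_id[om$n_retained == 0]
  expect_true(all(is.na(om$p_acat[match(not_ret, om$unit_id)])))
  # units with one retained strategy: omnibus equals that strategy's p
  one <- om$unit_id[om$n_retained == 1]
  for (u in one) {
    d <- res[res$unit_id == u & res$retained, ]
    expect_equal(om$p_acat[om$unit_id == u], d$p, tolerance = 1e-12)
  }
  # identical p across strategies collapses to the same p
  expect_equal(acat_combine(rep(0.2, 4)), 0.2, tolerance = 1e-12)
  # Bonferroni over units with at least one retained strategy
  expect_equal(us$summary$bonferroni,
               0.05 / sum(!is.na(om$p_acat)))
})

test_that("SNV-only and INDEL-only qualifying sets partition the full set", {
  co <- burden_fixture(33)
  q_all <- qualify_variants(co$genotypes, co$variants, "ultrarare",
                            "high_moderate")
  snv <- co$variants$vtype == "SNV"
  q_snv <- qualify_variants(co$genotypes[, snv, drop = FALSE],
                            co$variants[snv, , drop = FALSE],
                            "ultrarare", "high_moderate")
  q_ind <- qualify_variants(co$genotypes[, !snv, drop = FALSE],
                            co$variants[!snv, , drop = FALSE],
                            "ultrarare", "high_moderate")
  expect_setequal(c(q_snv, q_ind), q_all)
  expect_length(intersect(q_snv, q_ind), 0)
})

test_that("CDS mapping handles exact, near-border and far positions", {
  tr <- list(exons = data.frame(start = c(101, 201), end = c(150, 260)),
             strand = "+")
  expect_equal(map_to_cds(tr, 101), 1L)               # first coding base
  expect_equal(map_to_cds(tr, 150), 50L)
  expect_equal(map_to_cds(tr, 201), 51L)
  expect_equal(map_to_cds(tr, 162), 50L)              # 12 bp past exon 1 end
  expect_equal(map_to_cds(tr, 163), NA_integer_)      # 13 bp away
  expect_equal(map_to_cds(tr, 189), 51L)              # 12 bp before exon 2
  expect_equal(map_to_cds(tr, 89), 1L)                # 12 bp upstream (UTR)
  expect_equal(map_to_cds(tr, 88), NA_integer_)
  # minus strand reverses the numbering
  trm <- list(exons = tr$exons, strand = "-")
  expect_equal(map_to_cds(trm, 260), 1L)
  expect_equal(map_to_cds(trm, 101), 110L)
  expect_error(map_to_cds(list(exons = data.frame(start = c(1, 40),
                                                  end = c(50, 90)),
                               strand = "+"), 10), "overlapping")
})

test_that("domain units apply the 90% span rule and CDS containment", {
  gm <- data.frame(gene = "G1", transcript = "T1", cds_len = 1000L)
  v <- data.frame(variant_id = c("a", "b", "c"), gene = "G1",
                  impact = "HIGH", cds_pos = c(100L, 500L, 901L))
  doms <- data.frame(transcript = "T1",
                     domain_id = c("narrow", "at90", "wide"),
                     cds_start = c(50L, 1L, 1L),
                     cds_end = c(550L, 900L, 951L))
  units <- build_domain_units(doms, gm, v)
  ids <- vapply(units, function(u) u$unit_id, "")
  expect_setequal(ids, c("T1:narrow", "T1:at90"))     # 95.1% span dropped
  narrow <- units[[match("T1:narrow", ids)]]
  expect_setequal(narrow$members, c("a", "b"))
  expect_error(build_domain_units(
    data.frame(transcript = "T1", domain_id = "bad", cds_start = 0L,
               cds_end = 10L), gm, v), "outside CDS")
})

test_that("geneset loading applies size bounds after deduplication", {
  v <- data.frame(variant_id = sprintf("v%03d", 1:200),
                  gene = rep(sprintf("g%03d", 1:100), each = 2),
                  impact = "HIGH")
  sets <- list(small = sprintf("g%03d", 1:4),
               dup6 = rep("g001", 6),
               ok = sprintf("g%03d", 1:10),
               off_universe = c(sprintf("g%03d", 1:5), "not_a_gene"))
  units <- load_genesets(sets, v)
  ids <- vapply(units, function(u) u$unit_id, "")
  expect_setequal(ids, c("ok", "off_universe"))
  off <- units[[match("off_universe", ids)]]
  expect_length(off$genes, 5)            # unknown gene dropped before sizing
  # GMT parsing errors carry the line number
  f <- withr::local_tempfile(lines = c("s1\tdesc\tg001", "broken_line"))
  expect_error(read_gmt(f), "line 2")
})

test_that("conditional tests attenuate shared signal but keep independent signal", {
  cfg <- sim_config(n_cases = 300, n_controls = 1500, n_genes = 10, seed = 40,
                    variants_per_gene = list(mean = 12),
                    maf_spectrum = list(min = 2e-4, max = 0.01),
                    effect_spec = data.frame(gene = "G0002", maf = 8e-4,
                                             or = 8, impact = "HIGH",
                                             n_variants = 5))
  co <- simulate_cohort(cfg)
  ua <- co$units$genes[["G0002"]]
  empty <- functional_unit("empty", "gene", "not_a_variant")
  # a background gene that itself carries qualifying (null) variants
  qual0 <- qualify_variants(co$genotypes, co$variants, "ultrarare",
                            "high_moderate")
  bg <- setdiff(names(co$units$genes), "G0002")
  bg_carriers <- vapply(bg, function(g)
    sum(burden_score(co$genotypes, co$units$genes[[g]], qual0) > 0), 0)
  null_gene <- co$units$genes[[bg[which.max(bg_carriers)]]]

  # conditioning on a zero-carrier unit reproduces the unconditional test
  un_a <- conditional_unit_test(co$genotypes, co$samples, ua, empty,
                                co$variants, frequency = "ultrarare",
                                impact = "high_moderate")
  qual <- qualify_variants(co$genotypes, co$variants, "ultrarare",
                           "high_moderate")
  syn_q <- urvscan:::.qualifying_syn_count(co$genotypes, co$variants,
                                           "ultrarare")
  cv <- covariate_matrix(co$samples, syn_count = syn_q)
  X <- cbind(1, burden = burden_score(co$genotypes, ua, qual), cv)
  y <- as.numeric(co$samples$phenotype == 2L)
  expect_equal(un_a$p, penalized_lr_test(X, y, 2L)$p, tolerance = 1e-8)

  # superset whose signal sits entirely in the conditioning unit attenuates
  sup <- functional_unit("sup", "geneset",
                         c(ua$members, null_gene$members))
  un_sup <- conditional_unit_test(co$genotypes, co$samples, sup, empty,
                                  co$variants, frequency = "ultrarare",
                                  impact = "high_moderate")
  cond_sup <- conditional_unit_test(co$genotypes, co$samples, sup, ua,
                                    co$variants, frequency = "ultrarare",
                                    impact = "high_moderate")
  expect_gt(cond_sup$p, un_sup$p)
  expect_error(conditional_unit_test(co$genotypes, co$samples, ua, ua,
                                     co$variants), "indistinguishable")
})
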