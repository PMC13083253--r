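# Sample and variant quality control: hand-enumerated metrics, threshold
# filters, unrelated-set selection, exact HWE, QC flags, batch scan and
# duplicate concordance.

toy_variants <- function(ref, alt, vtype = NULL, chrom = NULL,
                         impact = "MODERATE") {
  n <- length(ref)
  if (is.null(vtype)) vtype <- ifelse(nchar(ref) > 1 | nchar(alt) > 1,
                                      "INDEL", "SNV")
  data.frame(variant_id = sprintf("v%02d", seq_len(n)),
             chrom = if (is.null(chrom)) rep("1", n) else chrom,
             pos = seq_len(n) * 100, ref = ref, alt = alt,
             gene = "G1", impact = impact, vtype = vtype,
             length = ifelse(vtype == "SNV", 1L, nchar(ref) - 1L))
}

test_that("sample metrics equal hand enumeration on a printed toy matrix", {
  # 3 samples x 4 variants: v1 A>G SNV (transition), v2 C>A SNV
  # (transversion), v3 AT>A INDEL, v4 T>C SNV (transition)
  G <- rbind(S1 = c(1L, 0L, 1L, 2L),
             S2 = c(0L, 1L, NA, 0L),
             S3 = c(0L, 0L, 0L, 2L))
  v <- toy_variants(c("A", "C", "AT", "T"), c("G", "A", "A", "C"))
  m <- sample_metrics(G, v)
  expect_equal(m$call_rate, c(1, 3 / 4, 1))
  expect_equal(m$n_snv, c(2, 1, 1))       # carried SNV variants
  expect_equal(m$n_indel, c(1, 0, 0))
  expect_equal(m$n_singleton, c(2, 1, 0)) # v1,v3 private to S1; v2 to S2
  # S1 carries v1 (ti) and v4 (ti): no transversions -> titv undefined
  expect_true(is.na(m$titv[1]))
  expect_equal(m$titv[2], 0)              # only v2 (tv): 0 ti / 1 tv
})

test_that("all-heterozygous sample at half-frequency sites gives F = -1", {
  # 4 samples heterozygous everywhere: pooled p = 0.5, expected het 0.5
  G <- matrix(1L, 4, 6, dimnames = list(paste0("S", 1:4), NULL))
  v <- toy_variants(rep("A", 6), rep("G", 6))
  m <- sample_metrics(G, v)
  expect_equal(m$het_f, rep(-1, 4))
})

test_that("zero-minor-allele samples get NA-safe F and zero counts", {
  G <- rbind(S1 = rep(0L, 5), S2 = c(1L, 1L, 0L, 0L, 0L))
  v <- toy_variants(rep("A", 5), rep("G", 5))
  m <- sample_metrics(G, v)
  expect_equal(m$n_snv[1], 0)
  expect_true(is.finite(m$het_f[1]))  # expected het > 0 from pooled freqs
  G0 <- matrix(0L, 2, 3, dimnames = list(c("a", "b"), NULL))
  m0 <- sample_metrics(G0, toy_variants(rep("A", 3), rep("G", 3)))
  expect_true(all(is.na(m0$het_f)))   # expected het exactly 0
})

test_that("sample filters apply the stated thresholds with reasons", {
  m <- data.frame(sample_id = c("a", "b", "c", "d"),
                  call_rate = c(0.89, 0.95, 1, 0.95),
                  het_f = c(0, 0.15, -0.05, -0.2),
                  n_snv = 1, n_indel = 0, n_singleton = 0,
                  titv = 2, indel_snv_ratio = 0)
  fs <- filter_samples(m)
  expect_setequal(fs$kept, c("c"))
  expect_match(fs$exclusions$reasons[fs$exclusions$sample_id == "a"],
               "call_rate<0.9")
  expect_match(fs$exclusions$reasons[fs$exclusions$sample_id == "b"], "F outside")
  # boundary: exactly 0.9 call rate and F exactly 0.1 pass
  m2 <- m; m2$call_rate <- 0.9; m2$het_f <- c(0.1, -0.1, 0, 0)
  expect_setequal(filter_samples(m2)$kept, c("a", "b", "c", "d"))
  # infinite thresholds keep everything
  fs3 <- filter_samples(m, list(call_rate_min = -Inf, f_range = c(-Inf, Inf)))
  expect_setequal(fs3$kept, m$sample_id)
})

test_that("unrelated-set selection follows the two-phase greedy rule", {
  nodes <- data.frame(sample_id = paste0("s", 1:7),
                      phenotype = c(2, 1, 1, 1, 1, 1, 1),
                      technology = "WGS")
  # star: hub s1 (a case) with degree 5 is removed in phase 1
  edges <- data.frame(sample_a = rep("s1", 5), sample_b = paste0("s", 2:6))
  kept <- select_unrelated(nodes, edges)
  expect_setequal(kept, paste0("s", 2:7))

  # duplicate case-control pair: control removed, case kept
  nodes2 <- data.frame(sample_id = c("case1", "ctrl1"),
                       phenotype = c(2, 1), technology = "WGS")
  edges2 <- data.frame(sample_a = "case1", sample_b = "ctrl1")
  expect_identical(select_unrelated(nodes2, edges2), "case1")

  # technology tie-break: WXS removed before WGS at equal phenotype
  nodes3 <- data.frame(sample_id = c("w1", "x1"), phenotype = c(2, 2),
                       technology = c("WGS", "WXS"))
  edges3 <- data.frame(sample_a = "w1", sample_b = "x1")
  expect_identical(select_unrelated(nodes3, edges3), "w1")

  # empty edge set retains everyone
  expect_setequal(select_unrelated(nodes, edges[0, ]), nodes$sample_id)
})

test_that("selected set is always edge-free on random graphs", {
  set.seed(5)
  for (r in 1:15) {
    n <- 30
    nodes <- data.frame(sample_id = sprintf("n%02d", 1:n),
                        phenotype = sample(1:2, n, TRUE),
                        technology = sample(c("WGS", "WXS"), n, TRUE))
    m <- sample(10:40, 1)
    edges <- unique(data.frame(
      sample_a = sample(nodes$sample_id, m, TRUE),
      sample_b = sample(nodes$sample_id, m, TRUE)))
    edges <- edges[edges$sample_a != edges$sample_b, ]
    kept <- select_unrelated(nodes, edges)
    expect_false(any(edges$sample_a %in% kept & edges$sample_b %in% kept))
  }
})

test_that("exact HWE test equals the enumeration oracle", {
  expect_equal(hwe_exact_test(2, 0, 2), 6 / 70)
  expect_equal(hwe_exact_test(7, 0, 0), 1)   # monomorphic
  expect_equal(hwe_exact_test(0, 0, 12), 1)
  set.seed(6)
  for (r in 1:200) {
    n <- sample(1:50, 1)
    cnt <- as.vector(rmultinom(1, n, c(0.5, 0.3, 0.2)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
})

test_that("variant QC flags implement the stated rules", {
  set.seed(9)
  n <- 40
  sm <- toy_samples(n)
  # v1: call rate 0.85 in WGS supercohort only; v2: 51-bp deletion;
  # v3: hwe (2,0,2) pattern in controls; v4: clean; v5: spanning deletion
  G <- matrix(0L, n, 5, dimnames = list(sm$sample_id, sprintf("v%02d", 1:5)))
  wgs <- which(sm$supercohort == "WGS")
  G[wgs[seq_len(ceiling(0.16 * length(wgs)))], 1] <- NA_integer_
  ctrl <- which(sm$phenotype == 1L)
  G[ctrl[1:2], 3] <- 2L  # two hom-alt, zero het among first 4 controls
  v <- toy_variants(c("A", paste0("A", strrep("T", 51)), "A", "A", "G"),
                    c("G", "A", "G", "G", "*"))
  rep <- variant_qc_mask(G, v, sm)
  expect_true(rep$call_rate_fail[1])
  expect_false(any(rep$call_rate_fail[2:5]))
  expect_true(rep$length_fail[2])
  expect_true(rep$spanning_del_fail[5])
  # (2,0,2)-style controls: p ~ several e-2 > 1e-4 -> no hwe flag
  expect_false(rep$hwe_fail[3])
  expect_equal(rep$pass, !(rep$call_rate_fail | rep$hwe_fail |
                             rep$length_fail | rep$spanning_del_fail |
                             rep$batch_fail))
  # idempotence: masking the passing subset flags nothing new
  keep <- rep$pass
  rep2 <- variant_qc_mask(G[, keep, drop = FALSE], v[keep, , drop = FALSE], sm)
  expect_true(all(rep2$pass))
  # 50-bp deletion is retained (strict > 50 rule)
  v50 <- toy_variants(paste0("A", strrep("T", 50)), "A")
  expect_false(variant_qc_mask(matrix(0L, n, 1), v50, sm)$length_fail)
})

test_that("control-control scan flags injected artifacts and merges small cohorts", {
  cfg <- sim_config(n_cases = 150, n_controls = 900, n_genes = 12,
                    maf_spectrum = list(min = 5e-3, max = 0.05), seed = 21)
  co <- simulate_cohort(cfg)
  co <- inject_batch_artifacts(co, data.frame(cohort = "UKB", n_variants = 4,
                                              missingness = 0,
                                              error_rate = 0.10))
  cc <- control_control_scan(co$genotypes, co$samples)
  bad <- cc$min_p[match(co$truth$batch$variant_id, cc$variant_id)]
  clean <- cc$min_p[!cc$variant_id %in% co$truth$batch$variant_id]
  expect_true(median(bad, na.rm = TRUE) <
                median(clean, na.rm = TRUE) / 100)
  expect_equal(unique(cc$n_contrasts), 3)

  # two 50-control cohorts merge into one pseudo-cohort: one less contrast
  sm <- co$samples
  ctrl_ids <- which(sm$phenotype == 1L & sm$cohort == "MISC")
  sm$cohort[ctrl_ids] <- rep_len(c("tiny1", "tiny2"), length(ctrl_ids))
  cc2 <- control_control_scan(co$genotypes[, 1:3], sm)
  expect_equal(unique(cc2$n_contrasts), 3)  # MINE, UKB, merged tinies

  # single cohort after merging errors
  sm2 <- co$samples; sm2$cohort <- "one"
  expect_error(control_control_scan(co$genotypes[, 1:2], sm2),
               "nothing to contrast")
})

test_that("duplicate concordance counts agreeing non-missing pairs", {
  G <- matrix(c(0L, 1L, 2L, 0L,
                0L, 1L, 2L, 1L,
                NA, 1L, 2L, 0L), 3, 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), sprintf("v%d", 1:4)))
  pairs <- data.frame(sample_a = c("a", "a"), sample_b = c("b", "c"))
  dc <- duplicate_concordance(G, pairs)
  expect_equal(dc$concordance, c(1, 1, 1, 0.5))
  expect_equal(dc$n_informative, c(1, 2, 2, 2))
  # duplicated row gives all-1 concordance
  dc2 <- duplicate_concordance(rbind(G, d = G["a", ]),
                               data.frame(sample_a = "a", sample_b = "d"))
  expect_equal(dc2$concordance, rep(1, 4))
  # all pairs missing at a variant -> undefined, not failed
  Gm <- G; Gm[c("a", "b", "c"), 1] <- NA_integer_
  dc3 <- duplicate_concordance(Gm, pairs)
  expect_true(is.na(dc3$concordance[1]))
  # one discordant pair of ten sits exactly on the 0.9 boundary
  G10 <- matrix(0L, 20, 1, dimnames = list(sprintf("p%02d", 1:20), "v1"))
  G10[2, 1] <- 1L  # second member of the first pair discordant
  p10 <- data.frame(sample_a = sprintf("p%02d", seq(1, 20, 2)),
                    sample_b = sprintf("p%02d", seq(2, 20, 2)))
  expect_equal(duplicate_concordance(G10, p10)$concordance, 0.9)
})
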