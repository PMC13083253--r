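# Dataset serialization: VCF v4.2 (GT only, biallelic), sample/variant/
# domain TSVs and GMT genesets. Reading goes through vcfR; writing emits
# plain text so datasets remain diffable and portable.

.gt_encode <- function(g, hemi) {
  out <- character(length(g))
  if (hemi) {
    out[is.na(g)] <- "."
    out[!is.na(g)] <- as.character(g[!is.na(g)])
  } else {
    out[is.na(g)] <- "./."
    out[!is.na(g) & g == 0L] <- "0/0"
    out[!is.na(g) & g == 1L] <- "0/1"
    out[!is.na(g) & g == 2L] <- "1/1"
  }
  out
}

.gt_decode <- function(gt) {
  g <- rep(NA_integer_, length(gt))
  g[gt %in% c("0/0", "0|0", "0")] <- 0L
  g[gt %in% c("0/1", "1/0", "0|1", "1|0", "1")] <- 1L
  g[gt %in% c("1/1", "1|1")] <- 2L
  g
}

#' Write a synthetic cohort to disk
#'
#' Emits `genotypes.vcf` (VCF v4.2, GT-only, one ALT per record; missing
#' genotypes as `./.`; hemizygous male chromosome-X genotypes as haploid
#' `0`/`1`), `samples.tsv`, `variants.tsv`, `genesets.gmt` and
#' `domains.tsv`. [read_dataset()] on the output directory reproduces the
#' in-memory genotype matrix, sample table and variant table exactly.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param directory output directory (created if needed).
#' @return manifest data frame with `file`, `path` and `n_records`.
#' @export
write_dataset <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  G <- cohort$genotypes
  sm <- cohort$samples
  vr <- cohort$variants
  male <- sm$sex == 1L

  vcf_path <- file.path(directory, "genotypes.vcf")
  header <- c("##fileformat=VCFv4.2",
              "##source=urvscan",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sm$sample_id), collapse = "\t"))
  body <- character(nrow(vr))
  for (v in seq_len(nrow(vr))) {
    hemi <- vr$chrom[v] == "X" & male
    gt <- character(nrow(sm))
    gt[hemi] <- .gt_encode(G[hemi, v], TRUE)
    gt[!hemi] <- .gt_encode(G[!hemi, v], FALSE)
    body[v] <- paste(c(vr$chrom[v], vr$pos[v], vr$variant_id[v], vr$ref[v],
                       vr$alt[v], ".", ".", ".", "GT", gt), collapse = "\t")
  }
  con <- file(vcf_path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)

  write_tsv <- function(df, name) {
    path <- file.path(directory, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  s_path <- write_tsv(sm, "samples.tsv")
  v_path <- write_tsv(vr, "variants.tsv")
  d_path <- write_tsv(cohort$units$domains, "domains.tsv")

  gmt_path <- file.path(directory, "genesets.gmt")
  sets <- cohort$units$genesets
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, gmt_path)

  data.frame(file = c("genotypes.vcf", "samples.tsv", "variants.tsv",
                      "domains.tsv", "genesets.gmt"),
             path = c(vcf_path, s_path, v_path, d_path, gmt_path),
             n_records = c(nrow(vr), nrow(sm), nrow(vr),
                           nrow(cohort$units$domains), length(sets)))
}

#' Read a dataset written by [write_dataset()]
#'
#' @param directory directory holding `genotypes.vcf`, `samples.tsv`,
#'   `variants.tsv`, `domains.tsv` and `genesets.gmt`.
#' @return list with `genotypes` (samples x variants integer matrix),
#'   `samples`, `variants`, `domains` and `genesets`.
#' @export
read_dataset <- function(directory) {
  sm <- utils::read.delim(file.path(directory, "samples.tsv"),
                          stringsAsFactors = FALSE)
  vr <- utils::read.delim(file.path(directory, "variants.tsv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  dm <- utils::read.delim(file.path(directory, "domains.tsv"),
                          stringsAsFactors = FALSE)
  gs <- read_gmt(file.path(directory, "genesets.gmt"))

  N <- nrow(sm)
  if (nrow(vr) == 0L) {
    G <- matrix(NA_integer_, N, 0, dimnames = list(sm$sample_id, NULL))
  } else {
    vcf <- vcfR::read.vcfR(file.path(directory, "genotypes.vcf"),
                           verbose = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    G <- apply(gt, 1, .gt_decode)
    if (is.null(dim(G))) G <- matrix(G, nrow = N)
    dimnames(G) <- list(colnames(gt), rownames(gt))
    G <- G[sm$sample_id, vr$variant_id, drop = FALSE]
    storage.mode(G) <- "integer"
  }
  list(genotypes = G, samples = sm, variants = vr, domains = dm,
       genesets = gs)
}

#' Read a GMT geneset file
#'
#' Tab-separated: set name, description, then member genes. Duplicated
#' genes within a set are collapsed.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": expected name, description and ",
           "at least one gene")
    nms[i] <- f[1]
    sets[[i]] <- unique(f[-(1:2)])
  }
  names(sets) <- nms
  sets
}
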