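# Readers and writers for the standard formats: VCF v4.2 genotypes,
# tab-separated annotation/covariate/audiogram/phecode/weight tables,
# and whole-cohort round-trips with a checksum manifest.

#' Write a genotype matrix as VCF v4.2
#'
#' Variant ids of the form `chrom:pos:ref:alt` become the VCF
#' coordinates; genotypes 0/1/2/NA are encoded as `0/0`, `0/1`, `1/1`,
#' `./.`. Read depth and alternate-read fraction matrices, when given,
#' are emitted per genotype as `DP` and `AD` (ref,alt counts).
#'
#' @param genotypes Integer matrix, variants x individuals, rownames
#'   `chrom:pos:ref:alt`, colnames sample ids.
#' @param path Output file path (plain text).
#' @param depth,alt_frac Optional matrices aligned to `genotypes`.
#' @return The path, invisibly.
#' @export
write_vcf <- function(genotypes, path, depth = NULL, alt_frac = NULL) {
  parts <- strsplit(rownames(genotypes), ":", fixed = TRUE)
  if (any(lengths(parts) != 4))
    stop_input("variant ids must be chrom:pos:ref:alt")
  chrom <- vapply(parts, `[`, "", 1)
  pos <- vapply(parts, `[`, "", 2)
  ref <- vapply(parts, `[`, "", 3)
  alt <- vapply(parts, `[`, "", 4)
  has_qc <- !is.null(depth) && !is.null(alt_frac)
  gt <- matrix(c("0/0", "0/1", "1/1")[genotypes + 1L],
               nrow(genotypes), ncol(genotypes))
  gt[is.na(genotypes)] <- "./."
  if (has_qc) {
    ad_alt <- round(depth * ifelse(is.na(alt_frac), 0, alt_frac))
    ad <- paste0(depth - ad_alt, ",", ad_alt)
    gt <- matrix(paste0(gt, ":", depth, ":", ad),
                 nrow(genotypes), ncol(genotypes))
  }
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (has_qc)
    header <- c(header,
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">")
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT",
                              colnames(genotypes)), collapse = "\t"))
  fmt <- if (has_qc) "GT:DP:AD" else "GT"
  body <- paste(chrom, pos, rownames(genotypes), ref, alt, ".", "PASS",
                ".", fmt, sep = "\t")
  body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a biallelic VCF into a genotype matrix
#'
#' Genotypes become 0/1/2 alternate-allele counts with `./.` as NA; the
#' variant id is `chrom:pos:ref:alt` (1-based positions preserved).
#' Multiallelic records are refused: split them upstream. Per-genotype
#' `DP`/`AD` fields, when present, are returned as depth and
#' alternate-read-fraction matrices.
#'
#' @param path VCF file (plain text or gzipped).
#' @return List: `genotypes`, `variants` (chrom/pos/ref/alt data frame),
#'   and optionally `depth`, `alt_frac`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) stop_input("no records in VCF")
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop_input("multiallelic record at line(s) ",
               paste(head(which(multi), 5), collapse = ", "),
               "; pre-split into biallelic records")
  vid <- sprintf("%s:%s:%s:%s", fix[, "CHROM"], fix[, "POS"],
                 fix[, "REF"], fix[, "ALT"])
  gt <- vcfR::extract.gt(v, element = "GT")
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt),
                 dimnames = list(vid, colnames(gt)))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  geno[clean %in% c("0/0")] <- 0L
  geno[clean %in% c("0/1", "1/0")] <- 1L
  geno[clean %in% c("1/1")] <- 2L
  out <- list(genotypes = geno,
              variants = data.frame(variant_id = vid,
                                    chrom = fix[, "CHROM"],
                                    pos = as.integer(fix[, "POS"]),
                                    ref = fix[, "REF"], alt = fix[, "ALT"],
                                    stringsAsFactors = FALSE))
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if (all(c("DP", "AD") %in% fmt)) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    ad <- vcfR::extract.gt(v, element = "AD")
    alt_n <- vapply(strsplit(as.vector(ad), ","), function(x)
      if (length(x) == 2) as.numeric(x[2]) else NA_real_, numeric(1))
    alt_n <- matrix(alt_n, nrow(ad), ncol(ad))
    af <- alt_n / dp
    af[!is.finite(af)] <- NA_real_
    dimnames(dp) <- dimnames(af) <- dimnames(geno)
    out$depth <- dp
    out$alt_frac <- af
  }
  out
}

TABLE_SCHEMAS <- list(
  audiograms = c("individual_id", "date", "ear", "conduction",
                 "frequency_hz", "threshold_db"),
  phecodes = c("individual_id", "phecode", "date"),
  covariates = c("individual_id", "sex", "age", "ancestry"),
  annotations = c("variant_id", "gene_id", "consequence", "revel",
                  "gnomad_afr_af", "gnomad_nfe_af"),
  prs_weights = c("variant_id", "effect_allele", "other_allele", "weight"),
  gene_set = c("gene_id", "inheritance"),
  common_variants = c("variant_id", "ref", "alt", "imputation_r2"))

#' Read and validate a typed analysis table
#'
#' @param path Tab-separated file with a header row.
#' @param type One of `"audiograms"`, `"phecodes"`, `"covariates"`,
#'   `"annotations"`, `"prs_weights"`, `"gene_set"`, `"common_variants"`.
#' @return Data frame; unknown columns are preserved.
#' @export
read_table <- function(path, type) {
  type <- match.arg(type, names(TABLE_SCHEMAS))
  df <- read.delim(path, stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(TABLE_SCHEMAS[[type]], names(df))
  if (length(missing))
    stop_input(type, " table lacks required column(s): ",
               paste(missing, collapse = ", "))
  if ("individual_id" %in% names(df))
    df$individual_id <- as.character(df$individual_id)
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits the rare genotypes as VCF v4.2 (with DP/AD when QC metrics were
#' simulated), every other component as tab-separated text (the dosage
#' matrix with individual ids in the first column), a truth file, and a
#' manifest of MD5 checksums.
#'
#' @param cohort An `hl_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop_input("cannot create directory ", dir)
  p <- function(f) file.path(dir, f)
  write_vcf(cohort$genotypes, p("rare_genotypes.vcf"),
            depth = cohort$depth, alt_frac = cohort$alt_frac)
  write_tsv(cohort$covariates, p("covariates.tsv"))
  write_tsv(cohort$annotations, p("annotations.tsv"))
  write_tsv(cohort$audiograms, p("audiograms.tsv"))
  write_tsv(cohort$phecodes, p("phecodes.tsv"))
  write_tsv(cohort$prs_weights, p("prs_weights.tsv"))
  write_tsv(cohort$common_variants, p("common_variants.tsv"))
  write_tsv(cohort$gene_set, p("gene_set.tsv"))
  dos <- data.frame(individual_id = rownames(cohort$dosages),
                    cohort$dosages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(dos, p("dosages.tsv"))
  truth <- data.frame(individual_id = names(cohort$truth$liability),
                      liability = unname(cohort$truth$liability),
                      burden_true = unname(cohort$truth$burden_true),
                      pta_worse = unname(cohort$truth$pta_worse),
                      degree_true = cohort$truth$degree_true,
                      audiogram_positive = cohort$truth$audiogram_positive,
                      phecode_status = cohort$truth$phecode_status,
                      has_audiogram = cohort$truth$has_audiogram,
                      stringsAsFactors = FALSE)
  write_tsv(truth, p("truth.tsv"))
  files <- list.files(dir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, p("manifest.tsv"))
  out <- list.files(dir, full.names = TRUE)
  invisible(setNames(out, basename(out)))
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return List with the same table components as an `hl_cohort`
#'   (`covariates`, `genotypes`, optional `depth`/`alt_frac`,
#'   `annotations`, `dosages`, `common_variants`, `audiograms`,
#'   `phecodes`, `prs_weights`, `gene_set`, `truth`).
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  vcf <- read_vcf(p("rare_genotypes.vcf"))
  dos <- read.delim(p("dosages.tsv"), check.names = FALSE,
                    stringsAsFactors = FALSE)
  dmat <- as.matrix(dos[, -1, drop = FALSE])
  rownames(dmat) <- as.character(dos$individual_id)
  list(covariates = read_table(p("covariates.tsv"), "covariates"),
       genotypes = vcf$genotypes,
       depth = vcf$depth,
       alt_frac = vcf$alt_frac,
       annotations = read_table(p("annotations.tsv"), "annotations"),
       dosages = dmat,
       common_variants = read_table(p("common_variants.tsv"),
                                    "common_variants"),
       audiograms = read_table(p("audiograms.tsv"), "audiograms"),
       phecodes = read_table(p("phecodes.tsv"), "phecodes"),
       prs_weights = read_table(p("prs_weights.tsv"), "prs_weights"),
       gene_set = read_table(p("gene_set.tsv"), "gene_set"),
       truth = read.delim(p("truth.tsv"), stringsAsFactors = FALSE))
}
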