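# Genotype QC and rare-variant qualification filters.
#
# A variant qualifies for burden analysis when it is rare in both gnomAD
# reference populations (AFR and NFE AF <= 0.001; absent treated as 0),
# rare in the cohort (AF < 0.01, computed after genotype QC), and
# predicted deleterious: a pLoF consequence (frameshift, stop-gain,
# canonical-splice) or a missense with REVEL > 0.6.

CONSEQUENCE_CLASSES <- c("frameshift", "stop-gain", "canonical-splice",
                         "missense", "synonymous")

#' Qualification filter configuration
#'
#' @param gnomad_af_max Maximum gnomAD AFR/NFE allele frequency; variants
#'   with either population AF strictly greater are removed (ties kept).
#' @param cohort_af_max Cohort allele-frequency cutoff; variants with
#'   cohort AF `>= cohort_af_max` are removed (strict `<` kept).
#' @param revel_min Missense variants qualify when REVEL is strictly
#'   greater than this.
#' @param plof_classes Consequence classes counted as predicted
#'   loss-of-function.
#' @param clinvar_pathogenic_labels ClinVar labels counted as pathogenic.
#' @return A list of class `qualification_config`.
#' @export
qualification_config <- function(gnomad_af_max = 0.001,
                                 cohort_af_max = 0.01,
                                 revel_min = 0.6,
                                 plof_classes = c("frameshift", "stop-gain",
                                                  "canonical-splice"),
                                 clinvar_pathogenic_labels = c(
                                   "Pathogenic", "Likely pathogenic",
                                   "Pathogenic/Likely pathogenic")) {
  structure(list(gnomad_af_max = gnomad_af_max,
                 cohort_af_max = cohort_af_max,
                 revel_min = revel_min,
                 plof_classes = plof_classes,
                 clinvar_pathogenic_labels = clinvar_pathogenic_labels),
            class = "qualification_config")
}

#' Per-genotype read-depth QC and variant-level call filters
#'
#' Sets genotypes with read depth below `min_depth` to missing, then
#' keeps only variants with at least one homozygous-alternate call, or at
#' least one heterozygous call supported by an alternate-read fraction of
#' at least `min_alt_frac`, among the surviving genotypes.
#'
#' @param genotypes Integer matrix, variants in rows, individuals in
#'   columns, entries in `{0, 1, 2, NA}`.
#' @param depth Matrix of per-genotype read depths, same shape.
#' @param alt_frac Matrix of per-genotype alternate-read fractions, same
#'   shape (only used at heterozygous calls; may be NA elsewhere).
#' @param min_depth Depth below which a genotype is set missing
#'   (default 7, i.e. fewer than seven reads).
#' @param min_alt_frac Minimum alternate-read fraction supporting a
#'   heterozygous call (default 0.15).
#' @return List with `genotypes` (QC'd matrix restricted to retained
#'   variants), `retained` (logical per input variant), `n_set_missing`.
#' @export
apply_genotype_qc <- function(genotypes, depth, alt_frac,
                              min_depth = 7, min_alt_frac = 0.15) {
  if (!identical(dim(genotypes), dim(depth)) ||
      !identical(dim(genotypes), dim(alt_frac)))
    stop_input("genotype, depth and alt-fraction matrices must be aligned")
  low <- !is.na(depth) & depth < min_depth
  n_set_missing <- sum(low & !is.na(genotypes))
  genotypes[low] <- NA_integer_
  hom <- rowSums(genotypes == 2L, na.rm = TRUE) > 0
  goodhet <- rowSums(genotypes == 1L & !is.na(alt_frac) &
                       alt_frac >= min_alt_frac, na.rm = TRUE) > 0
  retained <- hom | goodhet
  list(genotypes = genotypes[retained, , drop = FALSE],
       retained = retained, n_set_missing = n_set_missing)
}

#' Cohort allele frequency with missing-aware denominator
#'
#' AF = alternate allele count / (2 x number of non-missing genotypes).
#' Variants whose genotypes are all missing get `NA` and are flagged.
#'
#' @param genotypes Integer matrix, variants x individuals, in
#'   `{0, 1, 2, NA}`.
#' @return Numeric vector of per-variant allele frequencies (named by
#'   rownames).
#' @export
cohort_allele_frequency <- function(genotypes) {
  nonmiss <- rowSums(!is.na(genotypes))
  af <- rowSums(genotypes, na.rm = TRUE) / (2 * nonmiss)
  af[nonmiss == 0] <- NA_real_
  af
}

#' Qualify variants for burden analysis
#'
#' @param annotations Data frame with columns `variant_id`, `gene_id`,
#'   `consequence`, `revel` (NA except missense), `gnomad_afr_af`,
#'   `gnomad_nfe_af` (NA = absent from gnomAD, treated as 0), and
#'   optionally `clinvar` (NA = no record).
#' @param cohort_af Named numeric vector of cohort allele frequencies
#'   (names = variant ids) as from [cohort_allele_frequency()].
#' @param config A [qualification_config()].
#' @return Data frame of class `qualified_variants`: `variant_id`,
#'   `gene_id`, `reason` ("plof" or "missense-revel"),
#'   `clinvar_pathogenic`.
#' @export
qualify_variants <- function(annotations, cohort_af,
                             config = qualification_config()) {
  unknown <- setdiff(unique(annotations$consequence), CONSEQUENCE_CLASSES)
  if (length(unknown))
    stop_input("unknown consequence class: ", paste(unknown, collapse = ", "))
  af <- cohort_af[match(annotations$variant_id, names(cohort_af))]
  if (anyNA(af))
    stop_input("cohort AF missing for some annotated variants")
  afr <- replace_na(annotations$gnomad_afr_af, 0)
  nfe <- replace_na(annotations$gnomad_nfe_af, 0)
  rare_ref <- afr <= config$gnomad_af_max & nfe <= config$gnomad_af_max
  rare_cohort <- af < config$cohort_af_max
  plof <- annotations$consequence %in% config$plof_classes
  mis <- annotations$consequence == "missense" &
    !is.na(annotations$revel) & annotations$revel > config$revel_min
  keep <- rare_ref & rare_cohort & (plof | mis)
  clinvar <- if ("clinvar" %in% names(annotations)) annotations$clinvar
             else rep(NA_character_, nrow(annotations))
  out <- data.frame(
    variant_id = annotations$variant_id[keep],
    gene_id = annotations$gene_id[keep],
    reason = ifelse(plof[keep], "plof", "missense-revel"),
    clinvar_pathogenic = !is.na(clinvar[keep]) &
      clinvar[keep] %in% config$clinvar_pathogenic_labels,
    stringsAsFactors = FALSE)
  class(out) <- c("qualified_variants", "data.frame")
  out
}

#' Partition a qualified set into ClinVar-pathogenic and remainder
#'
#' @param qualified Output of [qualify_variants()].
#' @return List with disjoint data frames `pathogenic` and `other` whose
#'   union is the input set.
#' @export
clinvar_partition <- function(qualified) {
  list(pathogenic = qualified[qualified$clinvar_pathogenic, , drop = FALSE],
       other = qualified[!qualified$clinvar_pathogenic, , drop = FALSE])
}
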