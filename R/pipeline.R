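# End-to-end analysis pipeline: phenotyping -> genotype QC and variant
# qualification -> burden construction -> association scans with
# FDR -> score evaluation, reading a cohort directory and writing
# result tables plus a run manifest.

#' Run the full hearing-loss burden analysis
#'
#' Executes every analysis stage on a cohort directory (as written by
#' [write_cohort()], or any directory with the same file layout):
#' hybrid phenotype assignment, genotype QC (when DP/AD are present),
#' variant qualification, per-gene burdens, total-burden regressions
#' over variant subsets, the known-gene and exome-wide burden scans with
#' separate Benjamini-Hochberg correction, per-degree logistic
#' contrasts, Fisher carrier tests, the common-variant scan, PRS and
#' burden score evaluation, and (optionally) permutation calibration of
#' the case-carrier threshold. Identical inputs and seed give identical
#' outputs.
#'
#' @param dir Cohort input directory.
#' @param out_dir Output directory for result tables (created; NULL for
#'   no files).
#' @param seed Integer seed for permutation and bootstrap streams.
#' @param case_carrier_min Case-carrier filter for the exome-wide scan
#'   (default 25; known genes always use 0).
#' @param n_pcs Principal components in the covariate model (default 20).
#' @param calibrate Run permutation calibration of the exome-wide
#'   case-carrier threshold (default FALSE; adds runtime).
#' @param n_perms Permutations per calibration step.
#' @param qual_config A [qualification_config()].
#' @return A list of result objects (invisibly when `out_dir` given):
#'   `phenotypes`, `qualified`, `burdens`, `total_burden_tests`,
#'   `known_scan`, `exome_scan`, `degree_effects`, `fisher`, `gwas`,
#'   `lambda`, `score_eval`, `calibration`, `manifest`.
#' @export
run_pipeline <- function(dir, out_dir = NULL, seed = 1,
                         case_carrier_min = 25, n_pcs = 20,
                         calibrate = FALSE, n_perms = 10,
                         qual_config = qualification_config()) {
  co <- read_cohort(dir)
  log_counts <- list()

  # --- phenotyping
  phen <- assign_phenotype(co$audiograms, co$phecodes,
                           individual_ids = co$covariates$individual_id)
  phen <- phen[match(co$covariates$individual_id, phen$individual_id), ]
  labels <- binarize_case_control(phen)
  y <- ifelse(phen$included, phen$degree_hl, NA)
  log_counts$included <- sum(phen$included)
  log_counts$cases <- sum(labels == "case", na.rm = TRUE)
  # a degenerate phenotype (e.g. no audiograms: every included
  # individual is a degree-0 phecode control) skips the regressions
  informative <- sum(!is.na(y)) > 30 && var(y, na.rm = TRUE) > 0

  # --- genotype QC + qualification
  geno <- co$genotypes
  if (!is.null(co$depth) && !is.null(co$alt_frac)) {
    qc <- apply_genotype_qc(geno, co$depth, co$alt_frac)
    geno <- qc$genotypes
    log_counts$variants_dropped_qc <- sum(!qc$retained)
  }
  af <- cohort_allele_frequency(geno)
  ann <- co$annotations[co$annotations$variant_id %in% rownames(geno), ]
  qualified <- qualify_variants(ann, af, qual_config)
  log_counts$qualified_variants <- nrow(qualified)

  # --- burdens
  burdens <- gene_burden(geno, qualified)
  burdens <- burdens[match(co$covariates$individual_id,
                           rownames(burdens)), , drop = FALSE]
  known_genes <- co$gene_set$gene_id[co$gene_set$inheritance != "novel"]
  universe <- unique(co$annotations$gene_id)
  subsets <- list(
    all = unname(total_burden(burdens,
                              intersect(known_genes, colnames(burdens)))))
  for (cls in c("DFNA", "DFNB", "DFNA+B")) {
    g <- co$gene_set$gene_id[co$gene_set$inheritance == cls]
    subsets[[cls]] <- unname(total_burden(burdens,
                                          intersect(g, colnames(burdens))))
  }
  # ClinVar split within known HL genes
  known_q <- qualified[qualified$gene_id %in% known_genes, , drop = FALSE]
  kp <- clinvar_partition(known_q)
  ids <- co$covariates$individual_id
  subsets$clinvar <- row_total(gene_burden(geno, kp$pathogenic), ids)
  subsets$non_clinvar <- row_total(gene_burden(geno, kp$other), ids)

  cov <- regression_covariates(co$covariates, n_pcs = n_pcs)

  # --- total burden associations (Table 1 layout)
  tb <- if (!informative) NULL else
    do.call(rbind, lapply(names(subsets), function(s) {
      if (var(subsets[[s]][!is.na(y)]) == 0) return(NULL)
      tryCatch(linear_test(y, subsets[[s]], cov, id = s),
               error = function(e) NULL)
    }))

  # --- per-gene scans: known genes (case carriers > 0) and exome-wide
  is_known <- colnames(burdens) %in% known_genes
  empty_scan <- data.frame(id = character(), beta = numeric(),
                           se = numeric(), p = numeric(), n = integer())
  known_scan <- if (!informative) empty_scan else
    burden_scan(burdens[, is_known, drop = FALSE], y, cov,
                labels, case_carrier_min = 0)
  exome_scan <- if (!informative) empty_scan else
    burden_scan(burdens[, !is_known, drop = FALSE], y, cov,
                labels, case_carrier_min = case_carrier_min)

  # --- per-degree logistic contrasts
  degs <- if (!informative) NULL else
    suppressWarnings(degree_level_effects(
      list(all = subsets$all, clinvar = subsets$clinvar,
           non_clinvar = subsets$non_clinvar), phen, cov))

  # --- Fisher carrier tests on the binary phenotype
  fisher <- do.call(rbind, lapply(c("all", "clinvar", "non_clinvar"),
    function(s) {
      tab <- carrier_table(subsets[[s]], labels)
      data.frame(subset = s, case_carriers = tab[1, 1],
                 control_carriers = tab[2, 1],
                 case_rate = tab[1, 1] / sum(tab[1, ]),
                 control_rate = tab[2, 1] / sum(tab[2, ]),
                 p = fisher_carrier_test(tab), stringsAsFactors = FALSE)
    }))

  # --- GWAS
  gw <- if (!informative)
    data.frame(id = character(), beta = numeric(), se = numeric(),
               p = numeric(), n = integer(), maf = numeric()) else
    gwas(co$dosages, co$common_variants, y, cov)
  safe_lambda <- function(p) {
    p <- p[is.finite(p)]
    if (!length(p)) return(NA_real_)
    tryCatch(genomic_lambda(p), error = function(e) NA_real_)
  }
  lambda <- list(known = safe_lambda(known_scan$p),
                 exome = safe_lambda(exome_scan$p),
                 gwas = safe_lambda(gw$p))

  # --- calibration (optional)
  calib <- NULL
  if (calibrate) {
    # the case-carrier filter is fixed from the observed labels; only
    # the phenotype entering the regressions is permuted
    novel_b <- burdens[, !is_known, drop = FALSE]
    novel_cs <- carrier_summary(novel_b, labels)
    runner <- function(th, yy) {
      genes <- filter_genes_by_case_carriers(novel_cs, th)
      genes <- genes[apply(novel_b[, genes, drop = FALSE], 2, var) > 0]
      if (!length(genes)) return(numeric(0))
      ols_scan(yy, novel_b[, genes, drop = FALSE], cov)$p
    }
    calib <- permutation_calibration(runner, y,
                                     thresholds = seq(0, 50, by = 5),
                                     n_perms = n_perms, seed = seed)
  }

  # --- risk scores
  prs <- apply_prs(co$dosages, co$prs_weights, co$common_variants)
  scores <- list(PRS = as.numeric(prs), hl_burden = subsets$all)
  eval_tab <- if (!informative)
    data.frame(score = character(), ancestry = character(),
               subset = character(), delta_r2 = numeric(),
               n = integer()) else
    suppressWarnings(stratified_evaluation(
      y, cov, scores, ancestry = co$covariates$ancestry,
      audiogram = !is.na(phen$pta)))

  res <- list(phenotypes = phen, qualified = qualified, burdens = burdens,
              total_burden_tests = tb, known_scan = known_scan,
              exome_scan = exome_scan, degree_effects = degs,
              fisher = fisher, gwas = gw, lambda = lambda,
              score_eval = eval_tab, calibration = calib,
              counts = log_counts, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(phen, file.path(out_dir, "phenotypes.tsv"))
    write_tsv(as.data.frame(qualified),
              file.path(out_dir, "qualified_variants.tsv"))
    if (!is.null(tb)) write_tsv(tb, file.path(out_dir, "total_burden.tsv"))
    write_tsv(known_scan, file.path(out_dir, "known_gene_scan.tsv"))
    write_tsv(exome_scan, file.path(out_dir, "exome_scan.tsv"))
    if (!is.null(degs))
      write_tsv(degs, file.path(out_dir, "degree_effects.tsv"))
    write_tsv(fisher, file.path(out_dir, "fisher_carrier.tsv"))
    write_tsv(gw, file.path(out_dir, "gwas.tsv"))
    write_tsv(eval_tab, file.path(out_dir, "score_evaluation.tsv"))
    write_qq_data(known_scan$p, file.path(out_dir, "qq_known.tsv"))
    write_qq_data(exome_scan$p, file.path(out_dir, "qq_exome.tsv"))
    manifest <- data.frame(
      stage = c("phenotypes", "qualified", "known_scan", "exome_scan",
                "gwas"),
      rows = c(nrow(phen), nrow(qualified), nrow(known_scan),
               nrow(exome_scan), nrow(gw)),
      seed = seed, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      stringsAsFactors = FALSE)
    write_tsv(manifest, file.path(out_dir, "run_manifest.tsv"))
    res$manifest <- manifest
    return(invisible(res))
  }
  res
}

row_total <- function(burdens, ids) {
  if (is.null(dim(burdens)) || ncol(burdens) == 0)
    return(numeric(length(ids)))
  replace_na(unname(rowSums(burdens)[match(ids, rownames(burdens))]), 0)
}

# expected vs observed -log10 p for QQ plotting
write_qq_data <- function(p, path) {
  if (!length(p)) return(invisible(NULL))
  o <- sort(p)
  df <- data.frame(expected = -log10((seq_along(o) - 0.5) / length(o)),
                   observed = -log10(o))
  write_tsv(df, path)
}
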