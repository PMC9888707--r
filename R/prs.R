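# Polygenic and burden risk-score evaluation: score application with
# allele matching, incremental R^2 with bootstrap standard errors,
# ancestry/audiogram stratification, and top-decile risk stratification.

#' Apply per-allele polygenic score weights to dosages
#'
#' `score_i = sum_v w_v d_iv` over weight-file variants matched to dosage
#' variants by id. When the weight's effect allele is the dosage's
#' reference orientation the dosage is flipped as `2 - d`; an allele pair
#' that matches neither orientation is skipped and counted. Missing
#' dosages are imputed as twice the effect-allele frequency.
#'
#' @param dosages Numeric matrix, individuals x variants (ALT-dosage
#'   orientation), colnames = variant ids.
#' @param weights Data frame: `variant_id`, `effect_allele`,
#'   `other_allele`, `weight`.
#' @param variant_table Data frame with `variant_id`, `ref`, `alt` giving
#'   the dosage orientation.
#' @return Numeric per-individual score with attributes `n_used`,
#'   `n_skipped`.
#' @export
apply_prs <- function(dosages, weights, variant_table) {
  idx <- match(weights$variant_id, colnames(dosages))
  ref <- variant_table$ref[match(weights$variant_id,
                                 variant_table$variant_id)]
  alt <- variant_table$alt[match(weights$variant_id,
                                 variant_table$variant_id)]
  straight <- !is.na(idx) & weights$effect_allele == alt &
    weights$other_allele == ref
  flipped <- !is.na(idx) & weights$effect_allele == ref &
    weights$other_allele == alt
  usable <- straight | flipped
  score <- numeric(nrow(dosages))
  for (j in which(usable)) {
    d <- dosages[, idx[j]]
    if (anyNA(d)) d[is.na(d)] <- 2 * mean(d, na.rm = TRUE) / 2
    if (flipped[j]) d <- 2 - d
    score <- score + weights$weight[j] * d
  }
  attr(score, "n_used") <- sum(usable)
  attr(score, "n_skipped") <- sum(!usable)
  names(score) <- rownames(dosages)
  score
}

#' Incremental R^2 of a score over the covariate model
#'
#' Difference in ordinary-least-squares R^2 between the phenotype
#' regressed on covariates plus the score and on covariates alone, on
#' the same complete cases.
#'
#' @param y Numeric phenotype (NA = excluded).
#' @param covariates Covariate matrix ([regression_covariates()]), or
#'   NULL for an intercept-only base model.
#' @param score Per-individual score.
#' @return Incremental R^2 (length-1 numeric; 0 with a warning for a
#'   constant score).
#' @export
incremental_r2 <- function(y, covariates, score) {
  Z <- if (is.null(covariates)) matrix(1, length(y), 1) else
    cbind(1, as.matrix(covariates))
  keep <- complete.cases(Z) & !is.na(y) & !is.na(score)
  Z <- Z[keep, , drop = FALSE]; y <- y[keep]; s <- score[keep]
  if (var(s) == 0) {
    warning("constant score; incremental R^2 is 0")
    return(0)
  }
  tss <- sum((y - mean(y))^2)
  r2_base <- 1 - sum(qr.resid(qr(Z), y)^2) / tss
  r2_full <- 1 - sum(qr.resid(qr(cbind(Z, s)), y)^2) / tss
  r2_full - r2_base
}

#' Bootstrap standard error of a statistic over individuals
#'
#' Resamples individuals with replacement and returns the standard
#' deviation of the statistic across resamples.
#'
#' @param statistic Function `(index vector) -> numeric` evaluating the
#'   statistic on a resample of individuals.
#' @param n Number of individuals.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return Bootstrap standard error (length-1 numeric).
#' @export
bootstrap_se <- function(statistic, n, B = 1000, seed = 1) {
  if (B < 2) stop_input("'B' must be at least 2")
  if (n < 10) stop_input("too few individuals to bootstrap")
  set.seed(as.integer(seed))
  reps <- vapply(seq_len(B), function(b) {
    statistic(sample.int(n, n, replace = TRUE))
  }, numeric(1))
  sd(reps)
}

#' Incremental R^2 with bootstrap SE for one phenotype/score pair
#'
#' Convenience wrapper combining [incremental_r2()] and [bootstrap_se()].
#'
#' @inheritParams incremental_r2
#' @param B Bootstrap resamples (default 200).
#' @param seed Integer seed.
#' @return One-row data frame: `delta_r2`, `se`, `n`.
#' @export
score_evaluation <- function(y, covariates, score, B = 200, seed = 1) {
  Z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  keep <- !is.na(y) & !is.na(score) &
    (if (is.null(Z)) TRUE else complete.cases(Z))
  y <- y[keep]; score <- score[keep]
  Z <- if (is.null(Z)) NULL else Z[keep, , drop = FALSE]
  dr2 <- incremental_r2(y, Z, score)
  se <- bootstrap_se(function(i) {
    suppressWarnings(incremental_r2(
      y[i], if (is.null(Z)) NULL else Z[i, , drop = FALSE], score[i]))
  }, n = length(y), B = B, seed = seed)
  data.frame(delta_r2 = dr2, se = se, n = length(y))
}

#' Stratified predictive-power table for PRS and burden scores
#'
#' Computes incremental R^2 for each score within each ancestry stratum
#' (all / each ancestry label), overall and restricted to individuals
#' with audiograms — the standard layout for reporting biobank score
#' performance.
#'
#' @param y Numeric phenotype (NA = excluded).
#' @param covariates Covariate matrix.
#' @param scores Named list of per-individual score vectors (e.g.
#'   `list(PRS = ..., hl_burden = ...)`).
#' @param ancestry Character vector of ancestry labels.
#' @param audiogram Logical vector: has audiometric data.
#' @param min_n Strata smaller than this get `NA` (default 50).
#' @return Data frame: `score`, `ancestry`, `subset`, `delta_r2`, `n`.
#' @export
stratified_evaluation <- function(y, covariates, scores, ancestry,
                                  audiogram, min_n = 50) {
  cov <- if (is.null(covariates)) NULL else as.matrix(covariates)
  strata <- c("all", sort(unique(ancestry)))
  out <- list()
  for (sc in names(scores)) for (anc in strata)
    for (sub in c("all", "audiogram")) {
      sel <- (anc == "all" | ancestry == anc) &
        (sub == "all" | audiogram)
      n_ok <- sum(sel & !is.na(y))
      dr2 <- if (n_ok < min_n) NA_real_ else
        suppressWarnings(incremental_r2(
          y[sel], if (is.null(cov)) NULL else cov[sel, , drop = FALSE],
          scores[[sc]][sel]))
      out[[length(out) + 1]] <- data.frame(
        score = sc, ancestry = anc, subset = sub,
        delta_r2 = dr2, n = n_ok, stringsAsFactors = FALSE)
    }
  do.call(rbind, out)
}

#' Odds ratio for the joint top quantile of two scores
#'
#' Exposure is membership in the strict top `1 - q` tail of both score
#' distributions (or of a single score if `score_b` is NULL); outcome is
#' degree HL at or above `hl_threshold`. The odds ratio uses the
#' Haldane-Anscombe 0.5 correction when a cell is zero; the confidence
#' interval is the Woolf log-OR normal approximation.
#'
#' @param score_a,score_b Per-individual scores (`score_b = NULL` for
#'   single-score stratification, e.g. top 1% of the PRS).
#' @param degree_hl Numeric degree HL (NA = excluded).
#' @param q Quantile cutoff (default 0.90 for the top decile).
#' @param hl_threshold Outcome is degree HL `>= hl_threshold` (default 2).
#' @return List: `or`, `ci` (95%), `table` (2x2 exposure x outcome),
#'   `q`, `degenerate` (TRUE when the exposure rule is vacuous).
#' @export
top_decile_or <- function(score_a, score_b = NULL, degree_hl, q = 0.90,
                          hl_threshold = 2) {
  keep <- !is.na(degree_hl) & !is.na(score_a) &
    (is.null(score_b) | !is.na(score_b %||% score_a))
  a <- score_a[keep]
  exposure <- a > quantile(a, q)
  if (!is.null(score_b)) {
    b <- score_b[keep]
    exposure <- exposure & (b > quantile(b, q))
  }
  degenerate <- q <= 0 || all(exposure) || !any(exposure)
  if (!any(exposure)) stop_input("empty exposure group")
  outcome <- degree_hl[keep] >= hl_threshold
  tab <- table(exposure = factor(exposure, c(TRUE, FALSE)),
               outcome = factor(outcome, c(TRUE, FALSE)))
  m <- matrix(as.numeric(tab), 2, 2,
              dimnames = list(c("exposed", "unexposed"),
                              c("case", "control")))
  mc <- if (any(m == 0)) m + 0.5 else m
  or <- (mc[1, 1] * mc[2, 2]) / (mc[1, 2] * mc[2, 1])
  se_log <- sqrt(sum(1 / mc))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se_log)
  list(or = or, ci = ci, table = m, q = q, degenerate = degenerate)
}
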