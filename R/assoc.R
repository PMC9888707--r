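# Association testing and calibration machinery: covariate-adjusted
# linear and logistic burden tests, vectorized per-gene / per-variant
# scans, Fisher exact carrier tests, genomic inflation, permutation
# threshold calibration, Benjamini-Hochberg FDR, and replication
# statistics.

#' Build the standard covariate design
#'
#' Returns the numeric covariate matrix used throughout: sex, age, age^2
#' (derived from age, never supplied independently), and the leading
#' genetic principal components.
#'
#' @param covariates Data frame with columns `sex`, `age` and `PC1`,
#'   `PC2`, ... as produced by the cohort generator or read from file.
#' @param n_pcs Number of principal components to include (default 20).
#' @param add_age_sq Include the derived age^2 term (default TRUE).
#' @return Numeric matrix with one row per individual.
#' @export
regression_covariates <- function(covariates, n_pcs = 20,
                                  add_age_sq = TRUE) {
  cols <- list(sex = covariates$sex, age = covariates$age)
  if (add_age_sq) cols$age_sq <- covariates$age^2
  if (n_pcs > 0) {
    pcs <- paste0("PC", seq_len(n_pcs))
    missing <- setdiff(pcs, names(covariates))
    if (length(missing))
      stop_input("covariate table lacks ", paste(missing, collapse = ", "))
    for (p in pcs) cols[[p]] <- covariates[[p]]
  }
  out <- do.call(cbind, cols)
  rownames(out) <- covariates$individual_id
  out
}

assemble_design <- function(x, covariates, y) {
  cov <- if (is.null(covariates)) NULL else as.matrix(covariates)
  d <- cbind(x = x, cov)
  keep <- complete.cases(d) & !is.na(y)
  list(x = d[keep, 1], cov = d[keep, -1, drop = FALSE], y = y[keep],
       n = sum(keep))
}

check_full_rank <- function(mm) {
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    bad <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    stop_input("rank-deficient design; collinear columns: ",
               paste(bad, collapse = ", "))
  }
}

#' Covariate-adjusted linear (OLS) association test
#'
#' Ordinary least squares of `y` on `x` and covariates with listwise
#' deletion; the reported effect is the coefficient on `x` with the
#' classical two-sided Wald (t) p-value.
#'
#' @param y Numeric outcome (e.g. degree HL).
#' @param x Numeric predictor (burden count or dosage).
#' @param covariates Optional numeric matrix/data frame of covariates
#'   (see [regression_covariates()]).
#' @param id Label for the tested unit.
#' @return One-row data frame: `id`, `beta`, `se`, `p`, `n`.
#' @export
linear_test <- function(y, x, covariates = NULL, id = "x") {
  d <- assemble_design(x, covariates, y)
  if (var(d$x) == 0) stop_input("degenerate predictor: zero variance in x")
  mm <- cbind(`(Intercept)` = 1, x = d$x, d$cov)
  if (d$n <= ncol(mm)) stop_input("too few complete cases")
  check_full_rank(mm)
  fit <- lm(d$y ~ mm - 1)
  sm <- summary(fit)$coefficients
  data.frame(id = id, beta = sm["mmx", 1], se = sm["mmx", 2],
             p = sm["mmx", 4], n = d$n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Covariate-adjusted logistic association test
#'
#' Maximum-likelihood logistic regression (IRLS via [glm()]) with a Wald
#' two-sided p-value on the `x` coefficient. Complete separation is
#' flagged (diverging coefficient / exploding standard error) and the
#' p-value set missing.
#'
#' @inheritParams linear_test
#' @param y Binary outcome (0/1 or logical).
#' @return One-row data frame: `id`, `beta`, `se`, `p`, `n`, `separation`.
#' @export
logistic_test <- function(y, x, covariates = NULL, id = "x") {
  y <- as.numeric(y)
  d <- assemble_design(x, covariates, y)
  if (length(unique(d$y)) < 2) stop_input("both outcome classes required")
  if (var(d$x) == 0) stop_input("degenerate predictor: zero variance in x")
  mm <- cbind(`(Intercept)` = 1, x = d$x, d$cov)
  check_full_rank(mm)
  fit <- suppressWarnings(
    glm(d$y ~ mm - 1, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 100)))
  sm <- summary(fit)$coefficients
  beta <- sm["mmx", 1]; se <- sm["mmx", 2]
  sep <- !fit$converged || abs(beta) > 15 || se > 1e3
  data.frame(id = id, beta = beta, se = se,
             p = if (sep) NA_real_ else sm["mmx", 4],
             n = d$n, separation = sep,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Vectorized OLS of y on each column of X, adjusting for covariates by
# Frisch-Waugh-Lovell residualization. Exactly equals per-column lm().
ols_scan <- function(y, X, covariates = NULL) {
  Z <- if (is.null(covariates)) matrix(1, length(y), 1) else
    cbind(1, as.matrix(covariates))
  keep <- complete.cases(Z) & !is.na(y)
  Z <- Z[keep, , drop = FALSE]; y <- y[keep]
  X <- X[keep, , drop = FALSE]
  qz <- qr(Z)
  ry <- qr.resid(qz, y)
  rX <- qr.resid(qz, X)
  sxx <- colSums(rX^2)
  sxy <- colSums(rX * ry)
  beta <- sxy / sxx
  rss <- sum(ry^2) - beta^2 * sxx
  df <- length(y) - qz$rank - 1
  se <- sqrt(rss / df / sxx)
  tval <- beta / se
  data.frame(id = colnames(X) %||% seq_len(ncol(X)),
             beta = beta, se = se, p = 2 * pt(-abs(tval), df),
             n = length(y), row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene burden association scan
#'
#' Linear regression of the phenotype on each gene's burden with the
#' standard covariates, restricted to genes passing the case-carrier
#' filter. Carrier statistics and (optionally) Benjamini-Hochberg
#' q-values over the scanned genes are attached.
#'
#' @param burdens Individuals x genes burden matrix.
#' @param y Numeric phenotype (degree HL; NA = excluded).
#' @param covariates Covariate matrix ([regression_covariates()]).
#' @param labels Case/control labels for carrier statistics
#'   ([binarize_case_control()]).
#' @param case_carrier_min Genes must have strictly more case carriers
#'   than this (0 for known hearing-loss genes, 25 exome-wide).
#' @param fdr Attach BH q-values computed over the scanned genes.
#' @return Data frame: `id`, `beta`, `se`, `p`, `n`, `carriers`,
#'   `case_carriers`, `carrier_freq` and `q` if `fdr`.
#' @export
burden_scan <- function(burdens, y, covariates = NULL, labels = NULL,
                        case_carrier_min = 0, fdr = TRUE) {
  if (is.null(labels)) labels <- ifelse(is.na(y), NA, ifelse(y >= 2,
                                        "case", "control"))
  cs <- carrier_summary(burdens, labels)
  genes <- filter_genes_by_case_carriers(cs, case_carrier_min)
  genes <- genes[apply(burdens[, genes, drop = FALSE], 2, var) > 0]
  if (!length(genes))
    return(data.frame(id = character(), beta = numeric(), se = numeric(),
                      p = numeric(), n = integer()))
  res <- ols_scan(y, burdens[, genes, drop = FALSE], covariates)
  idx <- match(res$id, cs$gene_id)
  res$carriers <- cs$carriers[idx]
  res$case_carriers <- cs$case_carriers[idx]
  res$carrier_freq <- cs$carrier_freq[idx]
  if (fdr) res$q <- bh_adjust(res$p)
  res
}

#' Per-degree logistic contrasts of burden effects
#'
#' For each degree k in 1..4, fits a logistic regression of membership in
#' degree k versus degree 0 (phecode-derived controls included) on each
#' supplied burden vector, with covariates.
#'
#' @param burden_list Named list of per-individual burden vectors (e.g.
#'   all / ClinVar-only / excluding-ClinVar), or a single numeric vector.
#' @param phenotypes Output of [assign_phenotype()] aligned to the burden
#'   vectors.
#' @param covariates Covariate matrix aligned to the burden vectors.
#' @return Data frame: `stratum`, `degree`, `beta`, `se`, `p`, `n`,
#'   `separation`. Degrees with an empty group are skipped with a
#'   warning.
#' @export
degree_level_effects <- function(burden_list, phenotypes,
                                 covariates = NULL) {
  if (!is.list(burden_list)) burden_list <- list(all = burden_list)
  deg <- ifelse(phenotypes$included, phenotypes$degree_hl, NA)
  out <- list()
  for (k in 1:4) {
    in_k <- !is.na(deg) & deg == k
    in_0 <- !is.na(deg) & deg == 0
    if (!any(in_k)) {
      warning("degree ", k, " group empty; skipped")
      next
    }
    sel <- in_k | in_0
    cov_k <- if (is.null(covariates)) NULL else
      as.matrix(covariates)[sel, , drop = FALSE]
    for (s in names(burden_list)) {
      r <- tryCatch(
        logistic_test(in_k[sel], burden_list[[s]][sel], cov_k, id = s),
        error = function(e) {
          warning("degree ", k, ", stratum '", s, "' skipped: ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(r))
        out[[length(out) + 1]] <- cbind(stratum = s, degree = k,
                                        r[-1], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Two-sided Fisher exact test on a 2x2 carrier table
#'
#' Exact two-sided p-value summing hypergeometric probabilities of all
#' tables (margins fixed) no more probable than the observed one. A zero
#' margin returns p = 1 by convention, with a warning.
#'
#' @param tab 2x2 matrix of nonnegative integer counts (e.g. from
#'   [carrier_table()]).
#' @return The two-sided exact p-value.
#' @export
fisher_carrier_test <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2) || any(tab < 0) || any(tab != round(tab)))
    stop_input("'tab' must be a 2x2 matrix of nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin; p = 1 by convention")
    return(1)
  }
  fisher.test(tab)$p.value
}

#' Common-variant association scan (GWAS)
#'
#' Additive-dosage linear association of the phenotype with each common
#' variant, after minor-allele-frequency and imputation-quality filters.
#' Variants failing a filter are absent from the output.
#'
#' @param dosages Numeric matrix, individuals x variants, entries in
#'   `[0, 2]`, colnames = variant ids.
#' @param variant_table Data frame with `variant_id` and `imputation_r2`.
#' @param y Numeric phenotype.
#' @param covariates Covariate matrix.
#' @param maf_min Minimum minor allele frequency (default 0.01,
#'   strictly greater retained).
#' @param rsq_min Minimum imputation R^2 (default 0.30, strictly greater
#'   retained).
#' @return Data frame: `id`, `beta`, `se`, `p`, `n`, `maf`.
#' @export
gwas <- function(dosages, variant_table, y, covariates = NULL,
                 maf_min = 0.01, rsq_min = 0.30) {
  af <- colMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  rsq <- variant_table$imputation_r2[
    match(colnames(dosages), variant_table$variant_id)]
  keep <- maf > maf_min & !is.na(rsq) & rsq > rsq_min
  if (!any(keep))
    return(data.frame(id = character(), beta = numeric(), se = numeric(),
                      p = numeric(), n = integer(), maf = numeric()))
  res <- ols_scan(y, dosages[, keep, drop = FALSE], covariates)
  res$maf <- unname(maf[keep])
  res
}

#' Genomic inflation factor lambda
#'
#' Median of the 1-df chi-square statistics implied by the p-values,
#' divided by the theoretical chi-square(1) median 0.4549364.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Lambda (length-1 numeric).
#' @export
genomic_lambda <- function(p) {
  if (!length(p)) stop_input("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stop_input("p-values must lie in (0, 1]")
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Permutation-based threshold calibration
#'
#' Re-runs an association scan on permuted phenotypes along an increasing
#' grid of filter thresholds (case-carrier count, or minor-allele
#' frequency for a GWAS), computing the genomic inflation factor of the
#' permuted-phenotype p-values at each step (averaged over `n_perms`
#' permutations), and chooses the first threshold whose average lambda
#' does not exceed `lambda_max`. Covariates stay attached to individuals;
#' only the phenotype vector is permuted.
#'
#' @param test_runner Function `(threshold, phenotype) -> p-value vector`.
#' @param phenotype Numeric phenotype vector (NA allowed; permuted as a
#'   block so missingness moves with the values).
#' @param thresholds Strictly increasing numeric grid (e.g.
#'   `seq(0, 50, by = 5)` for case carriers or `c(.001, .005, .01)` for
#'   MAF).
#' @param lambda_max Largest acceptable average lambda (default 1.05).
#' @param n_perms Permutations averaged per threshold (default 10; 1
#'   reproduces a single-pass procedure).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `calibration_report`: `trajectory` (threshold,
#'   n_tests, lambda), `chosen` (threshold or NA), `lambda_max`,
#'   `n_perms`, `seed`.
#' @export
permutation_calibration <- function(test_runner, phenotype, thresholds,
                                    lambda_max = 1.05, n_perms = 10,
                                    seed = 1) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop_input("'thresholds' must be strictly increasing")
  set.seed(as.integer(seed))
  perms <- replicate(n_perms, sample.int(length(phenotype)),
                     simplify = FALSE)
  traj <- data.frame(threshold = numeric(), n_tests = integer(),
                     lambda = numeric())
  chosen <- NA_real_
  for (th in thresholds) {
    lams <- n_tests <- numeric(n_perms)
    for (b in seq_len(n_perms)) {
      p <- test_runner(th, phenotype[perms[[b]]])
      lams[b] <- if (length(p)) genomic_lambda(p) else NA_real_
      n_tests[b] <- length(p)
    }
    lam <- mean(lams)
    traj <- rbind(traj, data.frame(threshold = th,
                                   n_tests = as.integer(round(mean(n_tests))),
                                   lambda = lam))
    if (is.finite(lam) && lam <= lambda_max) { chosen <- th; break }
  }
  structure(list(trajectory = traj, chosen = chosen,
                 lambda_max = lambda_max, n_perms = n_perms, seed = seed),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Permutation threshold calibration (", x$n_perms,
      " permutations, seed ", x$seed, ")\n", sep = "")
  print(x$trajectory, row.names = FALSE)
  if (is.na(x$chosen))
    cat("No threshold reached lambda <=", x$lambda_max, "\n")
  else cat("Chosen threshold:", x$chosen,
           "(first with lambda <=", paste0(x$lambda_max, ")"), "\n")
  invisible(x)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} m p_(j) / j`, capped at
#' 1 and mapped back to input order. `m` may exceed the number of
#' supplied p-values when the remaining tests are known to have larger
#' p-values (they then never bind the step-up minimum).
#'
#' @param p Numeric p-values in (0, 1].
#' @param m Total number of tests (default `length(p)`).
#' @return Numeric q-values parallel to `p`.
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stop_input("p-values must lie in (0, 1]")
  if (m < length(p)) stop_input("'m' cannot be below length(p)")
  p.adjust(p, method = "BH", n = m)
}

#' Bonferroni minimum-p replication decision
#'
#' A gene replicates when the minimum p-value across the external
#' study's m models is below `alpha / m`.
#'
#' @param p P-values over the m models.
#' @param alpha Family-wise level (default 0.05).
#' @return List: `replicated`, `min_p`, `threshold`, `m`.
#' @export
bonferroni_min_p_replication <- function(p, alpha = 0.05) {
  if (!length(p)) stop_input("empty p-value vector")
  m <- length(p)
  list(replicated = min(p) < alpha / m, min_p = min(p),
       threshold = alpha / m, m = m)
}

#' Upper-tail binomial replication test
#'
#' Probability of observing at least `k` nominally significant results
#' among `n` independent look-ups when each succeeds with probability
#' `p0` (exact binomial tail).
#'
#' @param k Number of successes observed.
#' @param n Number of trials.
#' @param p0 Null success probability (default 0.05).
#' @return Upper-tail p-value `P(X >= k)`.
#' @export
binomial_replication <- function(k, n, p0 = 0.05) {
  if (p0 <= 0 || p0 >= 1) stop_input("'p0' must be in (0, 1)")
  if (k < 0 || k > n) stop_input("need 0 <= k <= n")
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}
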