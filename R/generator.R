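# Synthetic biobank generator with known ground truth.
#
# Emulates the data structure of an EHR biobank hearing-loss study:
# a two-ancestry cohort with genetic PCs, rare exome variants with
# deleteriousness annotations and population-specific frequencies,
# imputed common-variant dosages, a liability-scale phenotype driven by
# age/sex/PC/burden/PRS effects, per-ear per-frequency audiograms held
# by a small biased subset, and phecode billing records whose
# case/control labels are misclassified relative to audiometry at
# configurable rates.

#' Generator configuration
#'
#' Defaults encode the study conditions the pipeline is tested under: a
#' cohort of 20,000 (51% male, median age 58, 75% EUR / 25% AFR), 173
#' known hearing-loss genes plus novel genes, rare variant AFs below 1%,
#' ~5.3% audiogram coverage biased toward hearing loss, a phecode case
#' rate of 8.7% with 6.5% indeterminate, and EHR misclassification
#' calibrated so that 65% of phecode cases and 27% of phecode controls
#' with audiograms are audiogram-positive (worse-ear PTA > 25 dB).
#'
#' @param n_individuals Cohort size.
#' @param n_known_genes Known hearing-loss genes (drawn from the packaged
#'   synthetic gene list, max 173).
#' @param n_novel_genes Additional genes not on the known list.
#' @param variants_per_gene Mean rare variants per gene (count is
#'   `1 + Poisson(mean - 1)`).
#' @param rare_af_range Log-uniform support of per-variant allele
#'   frequencies (must lie within (0, 0.01)).
#' @param consequence_probs Named sampling probabilities over the five
#'   consequence classes (frameshift, stop-gain, canonical-splice,
#'   missense, synonymous).
#' @param male_fraction,age_mean,age_sd,age_range Demographics.
#' @param ancestry_weights Named mixture weights (must sum to 1).
#' @param n_common_variants,common_maf_range,rsq_range Common-variant
#'   panel: count, minor-allele-frequency floor/ceiling, imputation-R^2
#'   range.
#' @param n_prs_variants Common variants carrying nonzero truth PRS
#'   weights.
#' @param prs_flip_fraction Fraction of emitted weight rows stated on the
#'   reference-allele orientation (exercises allele flipping).
#' @param audiogram_fraction Proportion of the cohort with audiograms.
#' @param audiogram_bias Multiplicative selection factor for
#'   audiogram-positive individuals (hearing-loss-biased sampling).
#' @param audiogram_case_boost,audiogram_na_boost Selection multipliers
#'   for phecode cases / indeterminate individuals (audiograms are
#'   ordered for people whose charts mention hearing problems).
#' @param phecode_case_rate,phecode_na_rate Marginal phecode rates.
#' @param audiopos_given_case,audiopos_given_control Calibration targets:
#'   P(audiogram-positive | phecode case / control) among audiogram
#'   holders.
#' @param pta_loc,pta_scale PTA (dB HL) = loc + scale x standardized
#'   liability.
#' @param ear_sd,freq_sd Per-ear and per-frequency measurement noise (dB).
#' @param beta_total Liability effect per qualifying deleterious allele
#'   in known HL genes.
#' @param beta_gene Named vector of extra per-gene liability effects.
#' @param prs_share Share of liability variance carried by the polygenic
#'   score.
#' @param prs_afr_attenuation Multiplier on the PRS liability effect in
#'   AFR-ancestry individuals (1 = no attenuation; lower values emulate
#'   reduced cross-ancestry tagging).
#' @param beta_age,beta_age_sq,beta_sex,beta_pc1 Covariate liability
#'   effects (age terms per SD of age).
#' @param common_effects Named vector of direct liability effects of
#'   common variants (for power tests), by variant index or id.
#' @param noise_sd Residual liability SD, or NULL to complete total
#'   liability variance to 1.
#' @param simulate_qc_metrics Emit per-genotype read depth and
#'   alternate-read fractions (memory-heavy; default FALSE).
#' @param seed Root seed; all stages draw from named substreams.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 20000,
                          n_known_genes = 173,
                          n_novel_genes = 27,
                          variants_per_gene = 6,
                          rare_af_range = c(2e-4, 8e-3),
                          consequence_probs = c(frameshift = 0.08,
                                                `stop-gain` = 0.07,
                                                `canonical-splice` = 0.05,
                                                missense = 0.55,
                                                synonymous = 0.25),
                          male_fraction = 0.51,
                          age_mean = 58, age_sd = 16,
                          age_range = c(20, 90),
                          ancestry_weights = c(EUR = 0.75, AFR = 0.25),
                          n_common_variants = 400,
                          common_maf_range = c(0.002, 0.5),
                          rsq_range = c(0.2, 1),
                          n_prs_variants = 150,
                          prs_flip_fraction = 0.1,
                          audiogram_fraction = 0.053,
                          audiogram_bias = 1.35,
                          audiogram_case_boost = 38,
                          audiogram_na_boost = 2,
                          phecode_case_rate = 0.087,
                          phecode_na_rate = 0.065,
                          audiopos_given_case = 0.65,
                          audiopos_given_control = 0.27,
                          pta_loc = 14, pta_scale = 12.5,
                          ear_sd = 4, freq_sd = 5,
                          beta_total = 0.05,
                          beta_gene = NULL,
                          prs_share = 0.05,
                          prs_afr_attenuation = 1,
                          beta_age = 0.5, beta_age_sq = 0.1,
                          beta_sex = 0.12, beta_pc1 = 0.05,
                          common_effects = NULL,
                          noise_sd = NULL,
                          simulate_qc_metrics = FALSE,
                          seed = 1) {
  cfg <- as.list(environment())
  if (abs(sum(ancestry_weights) - 1) > 1e-8)
    stop_input("ancestry weights must sum to 1")
  if (n_individuals < 0) stop_input("'n_individuals' must be nonnegative")
  for (nm in c("male_fraction", "audiogram_fraction", "phecode_case_rate",
               "phecode_na_rate", "audiopos_given_case",
               "audiopos_given_control", "prs_share", "prs_flip_fraction"))
    check_prob(cfg[[nm]], nm)
  if (any(rare_af_range <= 0) || any(rare_af_range >= 0.01))
    stop_input("'rare_af_range' must lie within (0, 0.01)")
  if (any(common_maf_range <= 0) || any(common_maf_range > 0.5))
    stop_input("'common_maf_range' must lie within (0, 0.5]")
  structure(cfg, class = "cohort_config")
}

#' Simulate cohort demographics, ancestry and genetic PCs
#'
#' @param config A [cohort_config()].
#' @return Covariate data frame: `individual_id`, `sex` (1 = male),
#'   `age`, `ancestry`, `PC1`..`PC20`.
#' @export
simulate_individuals <- function(config) {
  n <- config$n_individuals
  set.seed(substream_seed(config$seed, "individuals"))
  w <- config$ancestry_weights
  ancestry <- sample(names(w), n, replace = TRUE, prob = w)
  age <- pmin(pmax(rnorm(n, config$age_mean, config$age_sd),
                   config$age_range[1]), config$age_range[2])
  pc_mu <- rbind(EUR = c(-0.012, -0.002, rep(0, 18)),
                 AFR = c(0.035, 0.010, rep(0, 18)))
  pcs <- matrix(rnorm(n * 20, sd = 0.01), n, 20)
  if (n > 0) pcs <- pcs + pc_mu[match(ancestry, rownames(pc_mu)), ]
  colnames(pcs) <- paste0("PC", 1:20)
  out <- data.frame(individual_id = sprintf("I%06d", seq_len(n)),
                    sex = rbinom(n, 1, config$male_fraction),
                    age = round(age, 1), ancestry = ancestry,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(pcs))
}

#' Simulate rare genotypes and their annotation table
#'
#' Per gene draws a variant count and per-variant allele frequencies
#' (log-uniform on the configured range) with ancestry-specific shifts;
#' genotypes are binomial(2, AF). Each variant is annotated with a
#' consequence class, a REVEL score (missense only), gnomAD AFR/NFE
#' frequencies correlated with the cohort AF, and an occasional ClinVar
#' label; per-genotype read depths and alternate-read fractions are
#' emitted when `simulate_qc_metrics` is set.
#'
#' @param config A [cohort_config()].
#' @param covariates Output of [simulate_individuals()].
#' @return List: `genotypes` (variants x individuals integer matrix),
#'   `annotations` (one row per variant), and optionally `depth`,
#'   `alt_frac` matrices.
#' @export
simulate_rare_genotypes <- function(config, covariates) {
  set.seed(substream_seed(config$seed, "rare"))
  n <- nrow(covariates)
  gs <- generator_gene_table(config)
  n_var <- 1L + rpois(nrow(gs), max(config$variants_per_gene - 1, 0))
  gene_of <- rep(gs$gene_id, n_var)
  m <- length(gene_of)
  lr <- log(config$rare_af_range)
  af <- exp(runif(m, lr[1], lr[2]))
  shift <- function() pmin(af * exp(rnorm(m, 0, 0.4)), 0.0095)
  af_pop <- cbind(EUR = shift(), AFR = shift())
  cons <- sample(CONSEQUENCE_CLASSES, m, replace = TRUE,
                 prob = config$consequence_probs)
  revel <- ifelse(cons == "missense", runif(m), NA_real_)
  deleterious <- cons %in% c("frameshift", "stop-gain", "canonical-splice") |
    (cons == "missense" & !is.na(revel) & revel > 0.6)
  clinvar <- rep(NA_character_, m)
  clin_draw <- runif(m)
  clinvar[deleterious & clin_draw < 0.05] <-
    sample(c("Pathogenic", "Likely pathogenic",
             "Pathogenic/Likely pathogenic"), sum(deleterious &
                                                  clin_draw < 0.05), TRUE)
  clinvar[!deleterious & clin_draw < 0.03] <- "Benign"
  pos <- sort(sample.int(2e8, m))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  vid <- sprintf("chr%d:%d:%s:%s", sample(1:22, m, TRUE), pos, ref, alt)

  p_ind <- af_pop[, match(covariates$ancestry, colnames(af_pop)),
                  drop = FALSE]
  if (is.null(dim(p_ind))) p_ind <- matrix(p_ind, nrow = m)
  geno <- matrix(rbinom(m * n, 2, p_ind), m, n)
  storage.mode(geno) <- "integer"
  rownames(geno) <- vid
  colnames(geno) <- covariates$individual_id

  ann <- data.frame(variant_id = vid, gene_id = gene_of,
                    consequence = cons, revel = revel,
                    gnomad_afr_af = pmax(af_pop[, "AFR"] *
                                           exp(rnorm(m, 0, 0.4)), 1e-6),
                    gnomad_nfe_af = pmax(af_pop[, "EUR"] *
                                           exp(rnorm(m, 0, 0.4)), 1e-6),
                    clinvar = clinvar, deleterious_truth = deleterious,
                    stringsAsFactors = FALSE)
  out <- list(genotypes = geno, annotations = ann)
  if (isTRUE(config$simulate_qc_metrics)) {
    depth <- matrix(rpois(m * n, 40), m, n,
                    dimnames = dimnames(geno))
    alt_frac <- matrix(NA_real_, m, n, dimnames = dimnames(geno))
    het <- which(geno == 1L)
    alt_frac[het] <- stats::rbeta(length(het), 20, 20)
    alt_frac[geno == 2L] <- 1
    alt_frac[geno == 0L] <- 0
    out$depth <- depth
    out$alt_frac <- alt_frac
  }
  out
}

generator_gene_table <- function(config) {
  known <- hl_gene_set()
  nk <- min(config$n_known_genes, nrow(known))
  known <- known[seq_len(nk), , drop = FALSE]
  known$known <- rep(TRUE, nk)
  if (config$n_novel_genes > 0) {
    novel <- data.frame(gene_id = sprintf("NOV%04d",
                                          seq_len(config$n_novel_genes)),
                        inheritance = "novel", known = FALSE,
                        stringsAsFactors = FALSE)
    rbind(known, novel)
  } else known
}

#' Simulate imputed common-variant dosages
#'
#' Dosages are hard genotypes plus imputation noise scaled by the
#' variant's imputation quality, clipped to `[0, 2]`; each variant
#' carries an imputation R^2 so quality filters are exercisable.
#'
#' @param config A [cohort_config()].
#' @param covariates Output of [simulate_individuals()].
#' @return List: `dosages` (individuals x variants), `variant_table`
#'   (`variant_id`, `ref`, `alt`, `maf_true`, `imputation_r2`).
#' @export
simulate_common_genotypes <- function(config, covariates) {
  set.seed(substream_seed(config$seed, "common"))
  n <- nrow(covariates)
  m <- config$n_common_variants
  maf <- runif(m, config$common_maf_range[1], config$common_maf_range[2])
  rsq <- runif(m, config$rsq_range[1], config$rsq_range[2])
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  vid <- sprintf("chr%d:%d:%s:%s", sample(1:22, m, TRUE),
                 sort(sample.int(2e8, m)), ref, alt)
  g <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m)
  noise <- matrix(rnorm(n * m, 0, rep(0.15 * sqrt(1 - rsq), each = n)),
                  n, m)
  d <- pmin(pmax(g + noise, 0), 2)
  dimnames(d) <- list(covariates$individual_id, vid)
  list(dosages = d,
       variant_table = data.frame(variant_id = vid, ref = ref, alt = alt,
                                  maf_true = maf, imputation_r2 = rsq,
                                  row.names = NULL,
                                  stringsAsFactors = FALSE))
}

# Truth PRS weights: nonzero on a random subset of common variants.
simulate_prs_weights <- function(config, variant_table) {
  set.seed(substream_seed(config$seed, "prs_weights"))
  m <- nrow(variant_table)
  k <- min(config$n_prs_variants, m)
  pick <- sort(sample.int(m, k))
  w <- rnorm(k) / sqrt(k)
  flip <- runif(k) < config$prs_flip_fraction
  emitted <- data.frame(
    variant_id = variant_table$variant_id[pick],
    effect_allele = ifelse(flip, variant_table$ref[pick],
                           variant_table$alt[pick]),
    other_allele = ifelse(flip, variant_table$alt[pick],
                          variant_table$ref[pick]),
    weight = ifelse(flip, -w, w), stringsAsFactors = FALSE)
  list(emitted = emitted,
       alt_oriented = setNames(w, variant_table$variant_id[pick]))
}

#' Simulate phenotypes: liability, audiograms and phecode records
#'
#' Builds the latent liability from age/sex/PC effects, the qualifying
#' deleterious allele burden in known hearing-loss genes, a polygenic
#' component with a configured liability-variance share, and Gaussian
#' noise; maps liability linearly to a true PTA; measures per-ear
#' per-frequency thresholds (5 dB steps) for both ears; and assigns
#' phecode instance counts and audiogram availability so that the
#' audiogram-positive rates among phecode cases and controls with
#' audiograms match the configured calibration targets.
#'
#' @param config A [cohort_config()].
#' @param covariates Output of [simulate_individuals()].
#' @param rare Output of [simulate_rare_genotypes()].
#' @param common Output of [simulate_common_genotypes()].
#' @return List: `audiograms` (holders only), `phecodes` (one row per
#'   billing instance), `truth` (liability, components, true burden,
#'   worse-ear PTA and degree for everyone, holder and status flags,
#'   PRS weights).
#' @export
simulate_phenotypes <- function(config, covariates, rare, common) {
  n <- nrow(covariates)
  set.seed(substream_seed(config$seed, "phenotype"))
  prs <- simulate_prs_weights(config, common$variant_table)

  # deleterious truth burden in known HL genes (allele counts)
  gs <- generator_gene_table(config)
  known_genes <- gs$gene_id[gs$known]
  ann <- rare$annotations
  causal <- ann$deleterious_truth & ann$gene_id %in% known_genes &
    ann$gnomad_afr_af <= 0.001 & ann$gnomad_nfe_af <= 0.001
  burden_true <- if (any(causal))
    colSums(rare$genotypes[causal, , drop = FALSE]) else numeric(n)

  cov_part <- if (n == 0) numeric(0) else {
    age_std <- (covariates$age - mean(covariates$age)) /
      max(sd(covariates$age), 1e-9)
    config$beta_age * age_std +
      config$beta_age_sq * (age_std^2 - 1) +
      config$beta_sex * (covariates$sex - mean(covariates$sex)) +
      config$beta_pc1 * scale_safe(covariates$PC1)
  }
  burden_part <- config$beta_total * (burden_true - mean(burden_true))
  if (!is.null(config$beta_gene) && length(config$beta_gene)) {
    for (g in names(config$beta_gene)) {
      rows <- which(ann$gene_id == g & causal)
      if (length(rows))
        burden_part <- burden_part + config$beta_gene[[g]] *
          colSums(rare$genotypes[rows, , drop = FALSE])
    }
  }
  common_part <- numeric(n)
  if (!is.null(config$common_effects) && length(config$common_effects)) {
    for (v in names(config$common_effects))
      common_part <- common_part +
        config$common_effects[[v]] * common$dosages[, v]
  }

  raw_score <- as.numeric(common$dosages[,
    names(prs$alt_oriented), drop = FALSE] %*% prs$alt_oriented)
  z <- scale_safe(raw_score)
  att <- ifelse(covariates$ancestry == "AFR",
                config$prs_afr_attenuation, 1)

  v_other <- var_safe(cov_part) + var_safe(burden_part) +
    var_safe(common_part)
  if (config$prs_share > 0) {
    if (is.null(config$noise_sd)) {
      noise_var <- 1 - v_other - config$prs_share
      if (noise_var <= 0.05)
        stop_input("configured effects leave too little residual variance;",
                   " set 'noise_sd' explicitly")
      v_prs <- config$prs_share
    } else {
      noise_var <- config$noise_sd^2
      v_prs <- config$prs_share * (v_other + noise_var) /
        (1 - config$prs_share)
    }
    prs_part <- sqrt(v_prs) * z * att
  } else {
    prs_part <- numeric(n)
    noise_var <- if (is.null(config$noise_sd))
      max(1 - v_other, 0.1) else config$noise_sd^2
  }
  liability <- cov_part + burden_part + common_part + prs_part +
    rnorm(n, 0, sqrt(noise_var))

  # latent audiograms for everyone; emitted only for holders
  l_std <- scale_safe(liability)
  pta_true <- config$pta_loc + config$pta_scale * l_std
  freqs <- c(250, 500, 1000, 2000, 4000, 8000)
  profile <- c(-5, -2, 0, 2, 8, 16)  # high-frequency sloping loss
  thr <- array(NA_real_, c(n, 2, length(freqs)))
  for (e in 1:2) {
    ear_off <- rnorm(n, 0, config$ear_sd)
    for (f in seq_along(freqs)) {
      raw <- pta_true + ear_off + profile[f] + rnorm(n, 0, config$freq_sd)
      thr[, e, f] <- pmin(pmax(round(raw / 5) * 5, -10), 110)
    }
  }
  pta_ear <- (thr[, , 2] + thr[, , 3] + thr[, , 4]) / 3  # 500/1k/2k Hz
  if (n == 1) pta_ear <- matrix(pta_ear, 1, 2)
  pta_worse <- if (n) pmax(pta_ear[, 1], pta_ear[, 2]) else numeric(0)
  audio_pos <- pta_worse > 25

  alloc <- allocate_phecode_audiogram(config, audio_pos)

  phecodes <- make_phecode_table(covariates$individual_id, alloc$status)
  audiograms <- make_audiogram_table(covariates$individual_id, thr, freqs,
                                     alloc$holder)
  truth <- list(liability = setNames(liability, covariates$individual_id),
                components = list(covariate = cov_part,
                                  burden = burden_part,
                                  common = common_part, prs = prs_part),
                burden_true = setNames(burden_true,
                                       covariates$individual_id),
                pta_worse = setNames(pta_worse, covariates$individual_id),
                degree_true = if (n) pta_to_degree(pta_worse)
                              else integer(0),
                audiogram_positive = audio_pos,
                phecode_status = alloc$status,
                has_audiogram = alloc$holder,
                prs_weights_alt = prs$alt_oriented,
                beta_total = config$beta_total,
                prs_share = config$prs_share)
  list(audiograms = audiograms, phecodes = phecodes,
       prs_weights = prs$emitted, truth = truth)
}

scale_safe <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

var_safe <- function(x) if (length(x) < 2) 0 else var(x)

# Solve phecode-status probabilities by Bayes from the calibration
# targets and the realized audiogram-positive rate, then jointly
# allocate (status, audiogram-holder) within each positivity stratum by
# largest-remainder rounding. The factorized selection weights
# (status boost x bias^positive) make the holder-conditional rates equal
# the configured targets by construction.
allocate_phecode_audiogram <- function(config, audio_pos) {
  n <- length(audio_pos)
  status <- rep(NA_character_, n)
  holder <- logical(n)
  if (n == 0)
    return(list(status = status, holder = holder))
  p_hat <- mean(audio_pos)
  r <- config$audiogram_bias
  gam <- config$phecode_case_rate
  nu <- config$phecode_na_rate
  ctl <- 1 - gam - nu
  odds_adj <- function(target) {
    o <- target / (1 - target) / r
    o / (1 + o)
  }
  a_case <- odds_adj(config$audiopos_given_case)
  a_ctrl <- odds_adj(config$audiopos_given_control)
  p_status <- function(a_rate, marginal, pos) {
    if (pos) a_rate * marginal / p_hat
    else (1 - a_rate) * marginal / (1 - p_hat)
  }
  for (pos in c(TRUE, FALSE)) {
    idx <- which(audio_pos == pos)
    s <- p_status(a_case, gam, pos)
    k <- p_status(a_ctrl, ctl, pos)
    na <- 1 - s - k
    if (na < 0) {
      warning("infeasible phecode calibration at realized ",
              "audiogram-positive rate ", round(p_hat, 3),
              "; probabilities clipped")
      na <- 0
      tot <- s + k
      s <- s / tot; k <- k / tot
    }
    b <- solve_audiogram_base(config, p_hat, c(s, k, na), a_case, a_ctrl)
    boost <- c(config$audiogram_case_boost, 1, config$audiogram_na_boost)
    h <- pmin(b * boost * ifelse(pos, r, 1), 1)
    cells <- as.vector(rbind(c(s, k, na) * h, c(s, k, na) * (1 - h)))
    counts <- balanced_counts(length(idx), cells)
    ord <- sample(idx)
    pos_in <- 1
    for (j in 1:3) {
      st <- c("case", "control", NA_character_)[j]
      for (hflag in c(TRUE, FALSE)) {
        cnt <- counts[(j - 1) * 2 + ifelse(hflag, 1, 2)]
        if (cnt > 0) {
          sel <- ord[pos_in:(pos_in + cnt - 1)]
          status[sel] <- st
          holder[sel] <- hflag
          pos_in <- pos_in + cnt
        }
      }
    }
  }
  list(status = status, holder = holder)
}

# Base selection probability solved so the expected holder fraction
# matches config$audiogram_fraction given the realized composition.
solve_audiogram_base <- function(config, p_hat, probs_pos, a_case, a_ctrl) {
  r <- config$audiogram_bias
  gam <- config$phecode_case_rate
  nu <- config$phecode_na_rate
  ctl <- 1 - gam - nu
  boost <- c(config$audiogram_case_boost, 1, config$audiogram_na_boost)
  # expected weight: sum over status of P(status, pos) * boost * r^pos
  w <- gam * boost[1] * (a_case * r + (1 - a_case)) +
    ctl * boost[2] * (a_ctrl * r + (1 - a_ctrl))
  na_rate <- 1 - gam - ctl
  a_na <- min(max((p_hat - a_case * gam - a_ctrl * ctl) /
                    max(na_rate, 1e-12), 0), 1)
  w <- w + na_rate * boost[3] * (a_na * r + (1 - a_na))
  config$audiogram_fraction / w
}

make_phecode_table <- function(ids, status) {
  if (!length(ids))
    return(data.frame(individual_id = character(), phecode = character(),
                      date = character(), stringsAsFactors = FALSE))
  n_inst <- integer(length(ids))
  is_case <- !is.na(status) & status == "case"
  n_inst[is_case] <- 2L + rpois(sum(is_case), 1.2)
  n_inst[is.na(status)] <- 1L
  keep <- n_inst > 0
  data.frame(individual_id = rep(ids[keep], n_inst[keep]),
             phecode = "389",
             date = rep(sample(seq(as.Date("2013-05-05"),
                                   as.Date("2021-02-25"), by = "day"),
                               sum(keep), replace = TRUE), n_inst[keep]),
             stringsAsFactors = FALSE)
}

make_audiogram_table <- function(ids, thr, freqs, holder) {
  hi <- which(holder)
  if (!length(hi))
    return(data.frame(individual_id = character(), date = character(),
                      ear = character(), conduction = character(),
                      frequency_hz = numeric(), threshold_db = numeric()))
  dates <- sample(seq(as.Date("2013-05-05"), as.Date("2021-02-25"),
                      by = "day"), length(hi), replace = TRUE)
  rows <- list()
  ears <- c("left", "right")
  for (e in 1:2) {
    air <- data.frame(
      individual_id = rep(ids[hi], each = length(freqs)),
      date = as.character(rep(dates, each = length(freqs))),
      ear = ears[e], conduction = "air",
      frequency_hz = rep(freqs, length(hi)),
      threshold_db = as.vector(t(matrix(thr[hi, e, ], length(hi)))),
      stringsAsFactors = FALSE)
    bone <- air[air$frequency_hz %in% c(500, 1000, 2000), , drop = FALSE]
    bone$conduction <- "bone"
    bone$threshold_db <- pmax(bone$threshold_db - 5, -10)
    rows[[length(rows) + 1]] <- air
    rows[[length(rows) + 1]] <- bone
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic cohort
#'
#' Runs all generator stages from one root seed and returns every
#' component plus the ground-truth record.
#'
#' @param config A [cohort_config()].
#' @return Object of class `hl_cohort`: `covariates`, `genotypes`,
#'   `annotations`, optional `depth`/`alt_frac`, `dosages`,
#'   `common_variants`, `audiograms`, `phecodes`, `prs_weights`,
#'   `gene_map`, `gene_set`, `truth`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  covariates <- simulate_individuals(config)
  rare <- simulate_rare_genotypes(config, covariates)
  common <- simulate_common_genotypes(config, covariates)
  ph <- simulate_phenotypes(config, covariates, rare, common)
  gs <- generator_gene_table(config)
  structure(list(
    covariates = covariates,
    genotypes = rare$genotypes,
    annotations = rare$annotations,
    depth = rare$depth,
    alt_frac = rare$alt_frac,
    dosages = common$dosages,
    common_variants = common$variant_table,
    audiograms = ph$audiograms,
    phecodes = ph$phecodes,
    prs_weights = ph$prs_weights,
    gene_map = rare$annotations[c("variant_id", "gene_id")],
    gene_set = gs,
    truth = ph$truth,
    config = config), class = "hl_cohort")
}

#' @export
print.hl_cohort <- function(x, ...) {
  cat("Synthetic hearing-loss cohort\n")
  cat("  individuals:     ", nrow(x$covariates), "\n")
  cat("  rare variants:   ", nrow(x$genotypes), "in",
      length(unique(x$annotations$gene_id)), "genes\n")
  cat("  common variants: ", ncol(x$dosages), "\n")
  cat("  audiogram holders:", sum(x$truth$has_audiogram), "\n")
  st <- x$truth$phecode_status
  cat("  phecode cases/controls/NA:", sum(st == "case", na.rm = TRUE),
      "/", sum(st == "control", na.rm = TRUE), "/", sum(is.na(st)), "\n")
  invisible(x)
}
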