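# Synthetic cohort generator: determinism, marginals, calibration.

test_that("a fixed seed reproduces the cohort exactly", {
  c1 <- simulate_cohort(quick_config(n = 300, seed = 42))
  c2 <- simulate_cohort(quick_config(n = 300, seed = 42))
  expect_identical(c1$covariates, c2$covariates)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$dosages, c2$dosages)
  expect_identical(c1$audiograms, c2$audiograms)
  expect_identical(c1$phecodes, c2$phecodes)
  expect_identical(c1$truth$liability, c2$truth$liability)
  c3 <- simulate_cohort(quick_config(n = 300, seed = 43))
  expect_false(identical(c1$truth$liability, c3$truth$liability))
})

test_that("an empty cohort is handled without error", {
  co <- simulate_cohort(quick_config(n = 0))
  expect_identical(nrow(co$covariates), 0L)
  expect_identical(ncol(co$genotypes), 0L)
  expect_identical(nrow(co$audiograms), 0L)
})

test_that("demographics match the configured mixture", {
  co <- simulate_cohort(quick_config(n = 8000, seed = 2))
  expect_equal(mean(co$covariates$sex), 0.51, tolerance = 0.03)
  expect_equal(mean(co$covariates$ancestry == "EUR"), 0.75,
               tolerance = 0.03)
  expect_equal(median(co$covariates$age), 58, tolerance = 2)
  expect_error(cohort_config(ancestry_weights = c(a = 0.6, b = 0.6)),
               "sum to 1")
})

test_that("genotype counts follow the binomial sampling law", {
  cfg <- quick_config(n = 10000, seed = 8, variants_per_gene = 5)
  co <- simulate_cohort(cfg)
  ann <- co$annotations
  # per-variant expected AF: mixture of the two population AFs is not
  # emitted, so check against the realized AF's own binomial bounds
  counts <- rowSums(co$genotypes)
  af_hat <- counts / (2 * ncol(co$genotypes))
  # cohort AF must stay near the gnomAD-correlated annotations (same
  # lognormal family) and well below the rare ceiling
  expect_true(all(af_hat < 0.02))
  # aggregated check: alt-allele count within 4 SE of Binomial(2n, af)
  n2 <- 2 * ncol(co$genotypes)
  p0 <- pmax(af_hat, 1 / n2)
  dev <- abs(counts - n2 * af_hat)
  expect_true(all(dev <= 4 * sqrt(n2 * p0 * (1 - p0)) + 1e-9))
  # annotation table conserves the variant count
  expect_identical(nrow(ann), nrow(co$genotypes))
  # essentially-zero AF yields essentially no alternate alleles
  co0 <- simulate_cohort(quick_config(n = 400, seed = 9,
                                      rare_af_range = c(1e-8, 2e-8)))
  expect_true(all(rowSums(co0$genotypes) <= 1))
})

test_that("dosages live in [0, 2] and common MAF tracks the truth", {
  co <- simulate_cohort(quick_config(n = 6000, seed = 10))
  expect_true(all(co$dosages >= 0 & co$dosages <= 2))
  af_hat <- colMeans(co$dosages) / 2
  tr <- co$common_variants$maf_true
  se <- sqrt(tr * (1 - tr) / (2 * nrow(co$dosages)))
  expect_true(mean(abs(af_hat - tr) <= 4 * se + 0.02) > 0.95)
  expect_true(all(co$common_variants$imputation_r2 >= 0 &
                    co$common_variants$imputation_r2 <= 1))
})

test_that("null effects leave burden uncorrelated with degree HL", {
  cfg <- quick_config(n = 5000, seed = 12, beta_total = 0, prs_share = 0)
  co <- simulate_cohort(cfg)
  r <- cor(co$truth$burden_true, co$truth$degree_true)
  expect_lt(abs(r), 3 / sqrt(5000))
})

test_that("noise-free single-gene liability makes degree monotone in burden", {
  cfg <- quick_config(n = 2000, seed = 13, beta_total = 1.5,
                      prs_share = 0, noise_sd = 0,
                      beta_age = 0, beta_age_sq = 0, beta_sex = 0,
                      beta_pc1 = 0, ear_sd = 0, freq_sd = 0,
                      variants_per_gene = 10,
                      rare_af_range = c(5e-4, 2e-3))
  co <- simulate_cohort(cfg)
  b <- co$truth$burden_true
  d <- co$truth$degree_true
  expect_gte(max(b), 1)
  for (k in sort(unique(b))[-1])
    expect_gte(min(d[b == k]), max(d[b < k]) - 0L)
  # group means strictly ordered where burden differs
  expect_true(all(diff(tapply(d, b, mean)) >= 0))
})

test_that("misclassification calibration holds at moderate size", {
  co <- simulate_cohort(quick_config(n = 6000, seed = 14))
  ph <- assign_phenotype(co$audiograms, co$phecodes,
                         co$covariates$individual_id)
  mc <- misclassification_rates(ph, co$phecodes)
  expect_equal(unname(mc$rates["case"]), 0.65, tolerance = 0.05)
  expect_equal(unname(mc$rates["control"]), 0.27, tolerance = 0.05)
})

test_that("audiogram holders approximate the configured fraction", {
  co <- simulate_cohort(quick_config(n = 6000, seed = 15))
  frac <- length(unique(co$audiograms$individual_id)) / 6000
  expect_equal(frac, 0.053, tolerance = 0.015)
  # audiogram-positive individuals are over-represented among holders
  pos_holders <- mean(co$truth$audiogram_positive[co$truth$has_audiogram])
  pos_all <- mean(co$truth$audiogram_positive)
  expect_gt(pos_holders, pos_all)
})

test_that("PRS share solves to the configured liability variance share", {
  co <- simulate_cohort(quick_config(n = 8000, seed = 16))
  v <- var(co$truth$components$prs) / var(co$truth$liability)
  expect_equal(v, 0.05, tolerance = 0.015)
})
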