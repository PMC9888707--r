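# Risk-score application and evaluation.

make_dosage_fixture <- function() {
  d <- cbind(`chr1:1:A:G` = c(0, 1, 2),
             `chr1:2:C:T` = c(2, 1, 0),
             `chr1:3:G:A` = c(1, 1, 1))
  rownames(d) <- paste0("I", 1:3)
  vt <- data.frame(variant_id = colnames(d),
                   ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                   imputation_r2 = 0.9, stringsAsFactors = FALSE)
  list(d = d, vt = vt)
}

test_that("PRS is a weighted effect-allele dosage sum with flipping", {
  fx <- make_dosage_fixture()
  w0 <- data.frame(variant_id = fx$vt$variant_id,
                   effect_allele = fx$vt$alt, other_allele = fx$vt$ref,
                   weight = c(0.5, 0, 0))
  s <- apply_prs(fx$d, w0, fx$vt)
  expect_equal(as.numeric(s), c(0, 0.5, 1.0))
  # zero weights -> zero scores
  wz <- w0; wz$weight <- 0
  expect_equal(as.numeric(apply_prs(fx$d, wz, fx$vt)), c(0, 0, 0))
  # flip identity: stating the weight on the reference orientation with
  # opposite sign shifts the score by a constant 2w
  wf <- data.frame(variant_id = fx$vt$variant_id[1],
                   effect_allele = fx$vt$ref[1],
                   other_allele = fx$vt$alt[1], weight = -0.5)
  sf <- apply_prs(fx$d, wf, fx$vt)
  s1 <- apply_prs(fx$d, w0[1, ], fx$vt)
  expect_equal(as.numeric(sf) - as.numeric(s1), rep(-2 * 0.5, 3))
  # irreconcilable alleles are skipped and counted
  wbad <- data.frame(variant_id = fx$vt$variant_id[1],
                     effect_allele = "T", other_allele = "C", weight = 1)
  sb <- apply_prs(fx$d, wbad, fx$vt)
  expect_equal(as.numeric(sb), c(0, 0, 0))
  expect_identical(attr(sb, "n_skipped"), 1L)
})

test_that("PRS application is linear in the weights", {
  fx <- make_dosage_fixture()
  w1 <- data.frame(variant_id = fx$vt$variant_id,
                   effect_allele = fx$vt$alt, other_allele = fx$vt$ref,
                   weight = c(0.3, -0.2, 0.1))
  w2 <- w1; w2$weight <- c(0.1, 0.5, -0.4)
  w12 <- w1; w12$weight <- w1$weight + w2$weight
  expect_equal(as.numeric(apply_prs(fx$d, w12, fx$vt)),
               as.numeric(apply_prs(fx$d, w1, fx$vt)) +
                 as.numeric(apply_prs(fx$d, w2, fx$vt)))
})

test_that("incremental R^2 has the right limits and affine invariance", {
  set.seed(31)
  n <- 2000
  y <- rnorm(n)
  # score equal to the phenotype explains everything
  expect_equal(incremental_r2(y, NULL, y), 1)
  # independent score explains nothing (up to sampling noise)
  expect_lt(incremental_r2(y, NULL, rnorm(n)), 0.01)
  # constant score warns and returns 0
  expect_warning(r0 <- incremental_r2(y, NULL, rep(1, n)), "constant")
  expect_equal(r0, 0)
  # affine rescaling leaves delta R^2 unchanged
  cov <- matrix(rnorm(2 * n), n, 2)
  s <- rnorm(n) + 0.2 * y
  expect_equal(incremental_r2(y, cov, s),
               incremental_r2(y, cov, 5 - 3 * s), tolerance = 1e-12)
  # in-sample delta R^2 of a nested OLS pair is nonnegative
  expect_gte(incremental_r2(y, cov, rnorm(n)), 0)
})

test_that("bootstrap SE is reproducible, zero when degenerate, ~1/sqrt(n)", {
  set.seed(32)
  n <- 800
  y <- rnorm(n); s <- 0.3 * y + rnorm(n)
  stat <- function(i) suppressWarnings(incremental_r2(y[i], NULL, s[i]))
  se1 <- bootstrap_se(stat, n, B = 50, seed = 5)
  se2 <- bootstrap_se(stat, n, B = 50, seed = 5)
  expect_identical(se1, se2)
  expect_error(bootstrap_se(stat, 5, B = 10), "too few")
  expect_error(bootstrap_se(stat, n, B = 1), "at least 2")
  # degenerate statistic has zero spread
  expect_equal(bootstrap_se(function(i) 0.42, n, B = 20, seed = 1), 0)
  # scaling check across n on the same generative law
  ses <- vapply(c(500, 2000, 8000), function(nn) {
    set.seed(nn)
    yy <- rnorm(nn); ss <- 0.3 * yy + rnorm(nn)
    bootstrap_se(function(i)
      suppressWarnings(incremental_r2(yy[i], NULL, ss[i])),
      nn, B = 60, seed = 2)
  }, numeric(1))
  ratio <- ses[1] / ses[3]
  expect_gt(ratio, sqrt(16) / 2.5)   # ~4x with slack
  expect_lt(ratio, sqrt(16) * 2.5)
})

test_that("stratified evaluation reproduces per-stratum increments", {
  set.seed(33)
  n <- 1200
  y <- rnorm(n)
  s <- 0.3 * y + rnorm(n)
  anc <- rep(c("EUR", "AFR"), each = n / 2)
  aud <- rep(c(TRUE, FALSE), n / 2)
  tab <- stratified_evaluation(y, NULL, list(PRS = s), anc, aud)
  # identical strata give identical delta R^2
  all_all <- tab$delta_r2[tab$ancestry == "all" & tab$subset == "all"]
  expect_equal(all_all, incremental_r2(y, NULL, s))
  eur <- tab$delta_r2[tab$ancestry == "EUR" & tab$subset == "all"]
  expect_equal(eur, incremental_r2(y[anc == "EUR"], NULL,
                                   s[anc == "EUR"]))
  # small strata are masked
  tab2 <- stratified_evaluation(y, NULL, list(PRS = s), anc, aud,
                                min_n = n + 1)
  expect_true(all(is.na(tab2$delta_r2)))
})

test_that("ancestry-attenuated PRS tagging yields lower AFR delta R^2", {
  worse <- 0
  for (seed in 1:8) {
    co <- simulate_cohort(quick_config(
      n = 3000, seed = seed, prs_afr_attenuation = 0.3,
      n_common_variants = 120, n_prs_variants = 80))
    prs <- apply_prs(co$dosages, co$prs_weights, co$common_variants)
    lia <- co$truth$liability
    anc <- co$covariates$ancestry
    d_eur <- incremental_r2(lia[anc == "EUR"], NULL, prs[anc == "EUR"])
    d_afr <- incremental_r2(lia[anc == "AFR"], NULL, prs[anc == "AFR"])
    worse <- worse + (d_afr < d_eur)
  }
  expect_gte(worse, 7)
})

test_that("top-decile odds ratio matches the hand-computed cross product", {
  # construct scores so the joint top decile is exactly 100 of 300 ...
  # exposure cells (10, 90 / 5, 195): 10 exposed cases, 90 exposed
  # controls, 5 unexposed cases, 195 unexposed controls
  n <- 300
  exposed <- c(rep(TRUE, 100), rep(FALSE, 200))
  set.seed(34)
  sa <- ifelse(exposed, 2, 0) + runif(n)
  sb <- sa
  outcome <- c(rep(2, 10), rep(0, 90), rep(2, 5), rep(0, 195))
  r <- top_decile_or(sa, sb, outcome, q = 1 - 100 / 300)
  expect_equal(r$or, (10 * 195) / (90 * 5), tolerance = 1e-9)
  expect_identical(unname(r$table["exposed", "case"]), 10)
  # null scores give OR near 1 on average
  set.seed(35)
  ors <- replicate(30, {
    y <- sample(c(0, 2), 2000, TRUE)
    top_decile_or(rnorm(2000), NULL, y)$or
  })
  expect_equal(mean(log(ors)), 0, tolerance = 0.15)
  # degenerate quantile flagged
  expect_error(top_decile_or(rep(1, 50), NULL, rep(0, 50)), "empty exposure")
})
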