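# Association tests, inflation diagnostics, FDR and replication
# statistics, each checked against an independent oracle.

test_that("linear test recovers an exact line and rejects degenerate input", {
  r <- linear_test(c(1, 3, 5, 7), c(0, 1, 2, 3))
  expect_equal(r$beta, 2)
  expect_lt(r$se, 1e-10)
  # orthogonal predictor -> beta 0
  y <- c(1, -1, 1, -1); x <- c(1, 1, -1, -1)
  expect_equal(linear_test(y, x)$beta, 0)
  expect_error(linear_test(y, rep(1, 4)), "zero variance")
  # collinear covariates named in the error
  cov <- cbind(a = c(1, 2, 3, 4, 5, 6), b = c(2, 4, 6, 8, 10, 12))
  expect_error(linear_test(rnorm(6), rnorm(6), cov), "collinear")
})

test_that("linear test matches the normal-equations oracle on a random design", {
  set.seed(11)
  n <- 50
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("c", 1:5)))
  y <- rnorm(n)
  r <- linear_test(y, X[, 1], X[, -1])
  o <- ols_oracle(y, X)
  expect_equal(r$beta, unname(o$beta[2]), tolerance = 1e-8)
  expect_equal(r$se, unname(o$se[2]), tolerance = 1e-8)
})

test_that("vectorized scan equals per-column lm fits exactly", {
  set.seed(12)
  n <- 120
  cov <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("z", 1:3)))
  X <- matrix(rpois(n * 6, 0.3), n, 6, dimnames = list(NULL, paste0("g", 1:6)))
  y <- rnorm(n)
  scan <- hlburden:::ols_scan(y, X, cov)
  for (j in 1:6) {
    fit <- summary(lm(y ~ X[, j] + cov))$coefficients
    expect_equal(scan$beta[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(scan$se[j], fit[2, 2], tolerance = 1e-10)
    expect_equal(scan$p[j], fit[2, 4], tolerance = 1e-10)
  }
})

test_that("logistic test equals the closed-form 2x2 log odds ratio", {
  # 30 exposed cases, 70 exposed controls, 20/180 unexposed
  x <- rep(c(1, 1, 0, 0), c(30, 70, 20, 180))
  y <- rep(c(1, 0, 1, 0), c(30, 70, 20, 180))
  r <- logistic_test(y, x)
  expect_equal(r$beta, log((30 * 180) / (70 * 20)), tolerance = 1e-6)
  expect_false(r$separation)
})

test_that("logistic MLE maximizes the likelihood (local grid oracle)", {
  set.seed(13)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  fit <- glm(y ~ x, family = binomial())
  r <- logistic_test(y, x)
  expect_equal(r$beta, unname(coef(fit)[2]), tolerance = 1e-8)
  loglik <- function(b0, b1) sum(y * (b0 + b1 * x) -
                                   log(1 + exp(b0 + b1 * x)))
  b0 <- unname(coef(fit)[1])
  center <- loglik(b0, r$beta)
  for (d in c(-0.05, -0.01, 0.01, 0.05)) {
    expect_lt(loglik(b0 + d, r$beta), center + 1e-9)
    expect_lt(loglik(b0, r$beta + d), center + 1e-9)
  }
})

test_that("complete separation is flagged with a missing p-value", {
  x <- c(rep(0, 10), rep(1, 10))
  y <- x
  r <- logistic_test(y, x + rnorm(20, sd = 1e-4))
  expect_true(r$separation)
  expect_true(is.na(r$p))
})

test_that("null logistic burden test is unbiased at large n", {
  set.seed(14)
  n <- 10000
  x <- rpois(n, 0.3)
  y <- rbinom(n, 1, 0.5)
  r <- logistic_test(y, x)
  expect_lt(abs(r$beta), 3 * r$se)
})

test_that("Fisher exact p equals full hypergeometric enumeration", {
  expect_equal(fisher_carrier_test(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_carrier_test(matrix(c(0, 10, 10, 0), 2)),
               2 / choose(20, 10), tolerance = 1e-12)
  tab <- matrix(c(1, 11, 9, 3), 2)
  expect_equal(fisher_carrier_test(tab), fisher_oracle(tab),
               tolerance = 1e-10)
  # all tables with margins <= 12 against the enumeration oracle
  set.seed(15)
  for (i in 1:50) {
    t2 <- matrix(sample(0:12, 4, TRUE), 2)
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) {
      expect_warning(p <- fisher_carrier_test(t2), "zero margin")
      expect_equal(p, 1)
    } else {
      expect_equal(fisher_carrier_test(t2), fisher_oracle(t2),
                   tolerance = 1e-9)
    }
  }
  expect_error(fisher_carrier_test(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("genomic lambda matches its closed form and null calibration", {
  # all p at the chi-square(1) median -> lambda 1
  expect_equal(genomic_lambda(rep(pchisq(qchisq(0.5, 1), 1,
                                         lower.tail = FALSE), 5)), 1)
  # all p = 0.3173 (chi-square 1) -> 1 / 0.4549
  expect_equal(genomic_lambda(rep(0.3173105, 3)), 1 / qchisq(0.5, 1),
               tolerance = 1e-4)
  # scale equivariance: doubling the chi-square doubles lambda
  set.seed(16)
  chi <- rchisq(2000, 1)
  p1 <- pchisq(chi, 1, lower.tail = FALSE)
  p2 <- pchisq(2 * chi, 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(p2), 2 * genomic_lambda(p1),
               tolerance = 1e-8)
  # uniform p -> lambda near 1
  set.seed(17)
  expect_equal(genomic_lambda(runif(1e5)), 1, tolerance = 0.02)
  expect_error(genomic_lambda(numeric(0)), "empty")
  expect_error(genomic_lambda(c(0.5, 0)), "0, 1")
})

test_that("BH step-up equals the O(m^2) definition oracle", {
  set.seed(18)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    m <- length(p) + sample(0:100, 1)
    expect_equal(bh_adjust(p, m), bh_oracle(p, m), tolerance = 1e-12)
  }
  expect_equal(bh_adjust(0.04), 0.04)
  # invariance to input permutation
  p <- runif(25)
  o <- sample(25)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
  # monotone in sorted order
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.1, 0.2), m = 1), "cannot")
})

test_that("Bonferroni min-p replication rule follows alpha/m", {
  r <- bonferroni_min_p_replication(c(8e-4, rep(0.5, 23)))
  expect_true(r$replicated)
  expect_equal(r$threshold, 0.05 / 24)
  r2 <- bonferroni_min_p_replication(c(0.011, rep(0.5, 23)))
  expect_false(r2$replicated)
  expect_true(bonferroni_min_p_replication(0.04)$replicated)
  expect_error(bonferroni_min_p_replication(numeric(0)), "empty")
})

test_that("binomial replication equals term-by-term summation", {
  expect_equal(binomial_replication(9, 45), sum(dbinom(9:45, 45, 0.05)),
               tolerance = 1e-12)
  expect_equal(binomial_replication(0, 45), 1)
  expect_equal(binomial_replication(3, 3, 0.5), 0.125)
  expect_error(binomial_replication(2, 3, 1.5), "p0")
  expect_error(binomial_replication(5, 3), "k <= n")
})

test_that("GWAS applies MAF and imputation-quality filters before testing", {
  set.seed(19)
  n <- 500
  d <- cbind(v1 = rbinom(n, 2, 0.3), v2 = rbinom(n, 2, 0.005),
             v3 = rbinom(n, 2, 0.25))
  vt <- data.frame(variant_id = c("v1", "v2", "v3"),
                   imputation_r2 = c(0.9, 0.9, 0.2))
  y <- rnorm(n)
  res <- gwas(d, vt, y)
  expect_identical(res$id, "v1")   # v2 fails MAF, v3 fails R^2
  # all qualities at 0.1 -> zero variants tested
  vt$imputation_r2 <- 0.1
  expect_identical(nrow(gwas(d, vt, y)), 0L)
})

test_that("an injected common-variant effect is the top GWAS hit", {
  set.seed(20)
  n <- 1500; m <- 40
  maf <- runif(m, 0.05, 0.5)
  d <- sapply(maf, function(f) rbinom(n, 2, f))
  colnames(d) <- paste0("v", 1:m)
  vt <- data.frame(variant_id = colnames(d), imputation_r2 = 0.99)
  hits <- replicate(20, {
    y <- 0.35 * d[, 7] + rnorm(n)
    res <- gwas(d, vt, y)
    res$id[which.min(res$p)]
  })
  expect_gte(mean(hits == "v7"), 0.9)
})

test_that("permutation calibration walks the grid and is reproducible", {
  set.seed(21)
  # runner: below threshold 3 produce inflated p, above produce uniform
  runner <- function(th, y) {
    m <- 400
    if (th < 3) pchisq(rchisq(m, 1) * 1.8, 1, lower.tail = FALSE)
    else runif(m)
  }
  rep1 <- permutation_calibration(runner, rnorm(50), thresholds = 1:4,
                                  n_perms = 5, seed = 9)
  rep2 <- permutation_calibration(runner, rnorm(50), thresholds = 1:4,
                                  n_perms = 5, seed = 9)
  expect_identical(rep1$trajectory, rep2$trajectory)
  expect_identical(rep1$chosen, rep2$chosen)
  expect_true(all(diff(rep1$trajectory$threshold) > 0))
  expect_gte(rep1$chosen, 3)
  expect_lte(rep1$trajectory$lambda[nrow(rep1$trajectory)], 1.05)
  # trajectory stops at the first passing threshold
  expect_identical(rep1$chosen,
                   rep1$trajectory$threshold[nrow(rep1$trajectory)])
  # no threshold passes -> chosen absent
  bad <- function(th, y) pchisq(rchisq(100, 1) * 3, 1, lower.tail = FALSE)
  repbad <- permutation_calibration(bad, rnorm(10), thresholds = 1:2,
                                    n_perms = 3, seed = 1)
  expect_true(is.na(repbad$chosen))
  expect_error(permutation_calibration(runner, rnorm(10), c(2, 1)),
               "increasing")
})

test_that("degree-level contrasts recover a graded burden effect", {
  set.seed(22)
  n <- 8000
  b <- rpois(n, 0.8)
  latent <- 0.9 * b + rnorm(n)
  deg <- pmin(pmax(floor(latent), 0), 4)
  ph <- data.frame(individual_id = as.character(seq_len(n)),
                   degree_hl = as.integer(deg), pta = NA, source = NA,
                   included = TRUE, exclusion_reason = NA)
  res <- degree_level_effects(list(all = b), ph, NULL)
  expect_setequal(res$degree, 1:4)
  # effect estimates are positive and increase with severity
  expect_true(all(res$beta > 0))
  expect_gt(res$beta[res$degree == 4], res$beta[res$degree == 1])
  # empty degree group is skipped with a warning
  ph0 <- ph
  ph0$degree_hl[ph0$degree_hl == 4L] <- 3L
  expect_warning(degree_level_effects(list(all = b), ph0, NULL),
                 "degree 4")
})
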