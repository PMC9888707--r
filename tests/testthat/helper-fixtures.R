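# Shared fixture builders. Everything is generated in code; no stored
# binary data.

# one individual's audiogram rows for one ear/exam
aud_rows <- function(id, date, ear, thresholds,
                     freqs = c(500, 1000, 2000), conduction = "air") {
  data.frame(individual_id = id, date = date, ear = ear,
             conduction = conduction, frequency_hz = freqs,
             threshold_db = thresholds, stringsAsFactors = FALSE)
}

# a small annotation table covering every consequence class
tiny_annotations <- function() {
  data.frame(
    variant_id = paste0("chr1:", 100 + 1:6, ":A:G"),
    gene_id = c("G1", "G1", "G2", "G2", "G3", "G3"),
    consequence = c("stop-gain", "missense", "frameshift", "missense",
                    "synonymous", "canonical-splice"),
    revel = c(NA, 0.8, NA, 0.59, NA, NA),
    gnomad_afr_af = c(0, 1e-4, 2e-3, 0, 0, NA),
    gnomad_nfe_af = c(0, 1e-4, 1e-4, 0, 0, NA),
    clinvar = c("Pathogenic", NA, NA, "Benign", NA, "Likely pathogenic"),
    stringsAsFactors = FALSE)
}

# genotype matrix matching tiny_annotations(): 6 variants x 8 people
tiny_genotypes <- function() {
  g <- matrix(0L, 6, 8,
              dimnames = list(paste0("chr1:", 100 + 1:6, ":A:G"),
                              paste0("I", 1:8)))
  g[1, 1:2] <- 1L          # stop-gain carriers
  g[2, 3] <- 2L            # hom missense
  g[3, 4:6] <- 1L          # frameshift (fails gnomAD AFR)
  g[4, 1] <- 1L            # low-REVEL missense
  g[6, 7] <- 1L            # splice carrier
  g
}

# small quick generator config for structural tests; ... overrides any
# default, including the smallness settings
quick_config <- function(n = 400, seed = 1, ...) {
  args <- list(n_individuals = n, n_known_genes = 10, n_novel_genes = 5,
               variants_per_gene = 4, n_common_variants = 40,
               n_prs_variants = 20, seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(cohort_config, args)
}

# brute-force OLS via normal equations (independent of lm and qr.resid)
ols_oracle <- function(y, X) {
  X <- cbind(1, X)
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(y) - ncol(X))
  se <- sqrt(diag(solve(xtx)) * s2)
  list(beta = drop(beta), se = se)
}

# full-enumeration two-sided Fisher p via hypergeometric table weights
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  prob <- function(x) choose(r1, x) * choose(r2, c1 - x) /
    choose(r1 + r2, c1)
  probs <- vapply(lo:hi, prob, numeric(1))
  obs <- prob(a)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# O(m^2) BH definition oracle
bh_oracle <- function(p, m = length(p)) {
  o <- order(p)
  ps <- p[o]
  k <- length(p)
  q <- numeric(k)
  for (i in seq_len(k)) {
    cands <- vapply(i:k, function(j) m * ps[j] / j, numeric(1))
    q[i] <- min(1, cands)
  }
  q[order(o)]
}
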