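# hlburden

Rare-variant gene-burden and polygenic analysis of adult-onset hearing
loss in EHR biobanks.

## The problem

Electronic-health-record phenotypes for hearing loss are unreliable:
billing-code (phecode) cases and controls disagree badly with audiometry
in the minority of a biobank that has audiograms. Studies in this
setting therefore use a hybrid phenotype — an ordinal *degree of hearing
loss* (degree HL, 0–4) graded from the worse-ear air-conduction
pure-tone average (PTA) where audiograms exist, with phecode-defined
controls kept conservatively at degree 0 elsewhere — and then ask
whether rare predicted-deleterious variation in known deafness genes
(DFNA/DFNB), exome-wide gene burdens, common variants, and polygenic
scores are associated with it.

`hlburden` implements that analysis chain for geneticists working with
linked exome + EHR cohorts:

* **Phenotyping** — PTA (mean of 500/1000/2000 Hz air-conduction
  thresholds), worse-ear selection, degree bins 0–15 / 16–25 / 26–40 /
  41–55 / 56+ dB, phecode case (≥2 instances) / control (0) / NA (1)
  status, and the hybrid assignment with exclusion bookkeeping.
* **Variant qualification** — depth-based genotype QC (<7 reads →
  missing; variants need a homozygote or a ≥15%-supported het), gnomAD
  AFR/NFE AF ≤ 0.001, cohort AF < 0.01, and deleteriousness: pLoF
  (frameshift, stop-gain, canonical-splice) or missense with
  REVEL > 0.6; ClinVar-pathogenic partitioning.
* **Burden testing** — per-gene allele-count burdens; OLS of degree HL
  on burden with sex, age, age², PCs 1–20; per-degree logistic
  contrasts; Fisher exact carrier tests; case-carrier gene filters
  (>0 for known HL genes, >25 exome-wide); genomic inflation λ;
  permutation calibration of carrier/MAF thresholds;
  Benjamini–Hochberg FDR per scan; Bonferroni min-p and exact binomial
  replication statistics; a common-variant scan with MAF and
  imputation-R² filters.
* **Risk scores** — PRS application with effect-allele matching and
  flipping, incremental R² with bootstrap SE, ancestry × audiogram
  stratification, and top-decile odds ratios.
* **Synthetic cohort** — a generator with known ground truth (latent
  liability, misclassified phecode labels calibrated so 65% of cases
  and 27% of controls with audiograms are audiogram-positive, biased
  audiogram availability, population-shifted rare AFs), used by the
  whole test suite.

## Worked example

```r
library(hlburden)

cfg <- cohort_config(n_individuals = 5000, seed = 1)
co  <- simulate_cohort(cfg)
co
#> Synthetic hearing-loss cohort
#>   individuals:      5000
#>   rare variants:    1170 in 200 genes
#>   common variants:  400
#>   audiogram holders: 264
#>   phecode cases/controls/NA: 435 / 4240 / 325

phen <- assign_phenotype(co$audiograms, co$phecodes,
                         co$covariates$individual_id)
misclassification_rates(phen, co$phecodes)$rates
#>  case control
#> 0.651   0.271
```

Among the 264 synthetic audiogram holders, 65.1% of phecode cases and
27.1% of phecode controls are audiogram-positive (worse-ear PTA >
25 dB) — the EHR misclassification structure the generator is
calibrated to. Qualification and a total-burden test:

```r
af <- cohort_allele_frequency(co$genotypes)
q  <- qualify_variants(co$annotations, af)
nrow(q)                                   # 170 qualifying of 1170 variants
b   <- gene_burden(co$genotypes, q)       # individuals x genes
cov <- regression_covariates(co$covariates)
y   <- ifelse(phen$included, phen$degree_hl, NA)
tot <- rowSums(b)[co$covariates$individual_id]; tot[is.na(tot)] <- 0
linear_test(y, unname(tot), cov, id = "hl_burden")
#>          id        beta         se         p    n
#> 1 hl_burden 0.007864063 0.01499765 0.6000592 4456
```

The effect estimate is per qualifying allele on the 0–4 degree scale; at
n = 5000 with a small injected effect it is (correctly) not
distinguishable from zero. `run_pipeline(dir, out_dir, seed)` chains all
stages on a cohort directory written by `write_cohort()` and emits
tab-separated result tables (total-burden tests, known-gene and
exome-wide scans with FDR, per-degree contrasts, Fisher tests, GWAS,
score evaluation, QQ data, run manifest). A thin command-line front end
lives at `inst/cli/hlburden.R`
(`Rscript hlburden.R simulate|phenotype|qualify|burden|associate|gwas|prs|replicate|run-all ...`).

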