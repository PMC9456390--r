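test_that("minor allele frequency matches hand counts", {
  expect_equal(minor_allele_frequency(c(0, 0, 0, 0)), 0)
  expect_equal(minor_allele_frequency(c(0, 1, 1, 2)), 0.5)
  expect_equal(minor_allele_frequency(c(0, 0, 0, 1)), 0.125)
  expect_equal(minor_allele_frequency(c(2, 2, NA, 1)), 1 / 6, tolerance = 1e-12)
  expect_error(minor_allele_frequency(c(NA, NA)), "non-missing")
})

test_that("exact HWE test matches the enumeration oracle and is symmetric", {
  expect_equal(hwe_exact_test(0, 0, 7), 1.0)
  expect_equal(hwe_exact_test(1, 2, 1), hwe_enum_oracle(1, 2, 1), tolerance = 1e-12)
  # property: random tables, total <= 50, vs oracle and under hom swap
  set.seed(101)
  for (i in 1:200) {
    cts <- as.vector(rmultinom(1, sample(1:50, 1), prob = runif(3)))
    p1 <- hwe_exact_test(cts[1], cts[2], cts[3])
    expect_equal(p1, hwe_enum_oracle(cts[1], cts[2], cts[3]), tolerance = 1e-12)
    expect_equal(p1, hwe_exact_test(cts[3], cts[2], cts[1]), tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("dosage r2 equals squared Pearson correlation, with degenerate NA", {
  d1 <- c(0, 1, 2, 0)
  expect_equal(ld_r2(d1, d1), 1)
  expect_equal(ld_r2(d1, 2 - d1), 1)
  d2 <- c(0, 1, 1, 1)
  expect_equal(ld_r2(d1, d2), cor(d1, d2)^2, tolerance = 1e-12)
  expect_true(is.na(ld_r2(c(1, 1, 1), c(0, 1, 2))))   # monomorphic
  expect_error(ld_r2(c(0, 1), c(0, 1, 2)), "length")
})

test_that("call-rate filter removes samples first, then variants", {
  d <- matrix(0L, 10, 100)
  d[, 2] <- 1L  # keep polymorphic irrelevant here
  G <- toy_genotypes(d, or = rep(1.1, 100))
  res <- call_rate_filter(G, qc_config())
  expect_identical(dim(res$genotypes$dosage), dim(d))  # complete -> unchanged

  d2 <- d
  d2[1, 1:4] <- NA  # sample call rate 0.96 < 0.97
  G2 <- toy_genotypes(d2, or = rep(1.1, 100))
  res2 <- call_rate_filter(G2, qc_config())
  expect_identical(res2$removed_samples, "S1")
  # variant call rates recomputed on retained samples: all complete again
  expect_length(res2$removed_variants, 0)

  d3 <- d
  d3[1:2, 5] <- NA  # variant 5 missing in 20% of samples
  G3 <- toy_genotypes(d3, or = rep(1.1, 100))
  res3 <- call_rate_filter(G3, qc_config())
  expect_identical(res3$removed_variants, "v5")
  expect_length(res3$removed_samples, 0)
})

test_that("greedy LD pruning keeps the first of duplicated columns", {
  set.seed(5)
  base <- sample(0:2, 50, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  other <- replicate(2, sample(0:2, 50, replace = TRUE, prob = c(0.25, 0.5, 0.25)))
  # variants 2 and 4 are copies of 1; expect 1/3/5 kept
  d <- cbind(base, base, other[, 1], base, other[, 2])
  G <- toy_genotypes(d, or = rep(1.1, 5))
  res <- ld_prune(G, qc_config())
  expect_setequal(res$removed_variants, c("v2", "v4"))

  # all-independent panel: nothing removed
  d_ind <- replicate(5, sample(0:2, 200, replace = TRUE, prob = c(0.25, 0.5, 0.25)))
  res_ind <- ld_prune(toy_genotypes(d_ind, or = rep(1.1, 5)), qc_config())
  expect_length(res_ind$removed_variants, 0)
})

test_that("LD pruning retains the higher-call-rate member of a pair", {
  set.seed(6)
  base <- sample(0:2, 60, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  d <- cbind(base, base)
  d[1:5, 1] <- NA  # first variant has the lower call rate
  G <- toy_genotypes(d, or = rep(1.1, 2))
  res <- ld_prune(G, qc_config())
  expect_identical(res$removed_variants, "v1")
})

test_that("Cochran Q and I2 follow the inverse-variance formulas", {
  res0 <- cochran_q(c(0.3, 0.3, 0.3), rep(0.1, 3))
  expect_equal(res0$Q, 0)
  expect_equal(res0$i2, 0)
  res1 <- cochran_q(c(0, 1), c(1, 1))
  expect_equal(res1$Q, 0.5, tolerance = 1e-12)   # weighted mean 0.5
  expect_equal(res1$df, 1)
  set.seed(8)
  eff <- rnorm(5); se <- runif(5, 0.1, 0.5)
  res2 <- cochran_q(eff, se)
  expect_equal(res2$i2, max(0, (res2$Q - 4) / res2$Q) * 100, tolerance = 1e-12)
  expect_error(cochran_q(1, 1), "two effects")
})

test_that("run_qc accounts for every removal and is idempotent", {
  cfg <- sim_config(n_samples = 400, n_snps = 60, seed = 91,
                    n_hwe_violators = 3, n_ld_duplicates = 2,
                    missing_rate = 0.002, maf_range = c(0.1, 0.45))
  cohort <- simulate_cohort(cfg)
  res <- run_qc(cohort$genotypes, qc_config(), phenotype = cohort$phenotype)
  rep1 <- res$report
  expect_equal(rep1$n_variants_out + nrow(rep1$removed), rep1$n_variants_in)
  expect_true(all(rep1$removed$reason %in% c("call_rate", "maf", "hwe", "ld")))
  expect_false(anyDuplicated(rep1$removed$variant_id) > 0)

  # idempotence: QC of QC output removes nothing
  res2 <- run_qc(res$genotypes, qc_config(), phenotype = cohort$phenotype)
  expect_equal(res2$report$n_variants_out, res2$report$n_variants_in)
  expect_equal(res2$report$n_samples_out, res2$report$n_samples_in)
})

test_that("run_qc on a clean HWE/LD-free panel retains all variants", {
  cfg <- sim_config(n_samples = 500, n_snps = 40, seed = 17,
                    n_hwe_violators = 0, n_ld_duplicates = 0,
                    missing_rate = 0, maf_range = c(0.2, 0.45))
  cohort <- simulate_cohort(cfg)
  # permissive alpha avoids chance HWE hits; checks MAF/call-rate/LD passes
  res <- run_qc(cohort$genotypes, qc_config(hwe_alpha = 1e-4))
  expect_equal(res$report$n_variants_out, 40)
})
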