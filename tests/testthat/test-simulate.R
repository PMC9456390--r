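test_that("simulation is bit-deterministic under a fixed seed", {
  cfg <- sim_config(n_samples = 150, n_snps = 40, seed = 71)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$weights, b$weights)
  c2 <- simulate_cohort(sim_config(n_samples = 150, n_snps = 40, seed = 72))
  expect_false(identical(a$genotypes$dosage, c2$genotypes$dosage))
})

test_that("panel frequencies and odds ratios respect their configured ranges", {
  cfg <- sim_config(n_samples = 100, n_snps = 200, n_causal = 50,
                    or_range = c(1.05, 1.5), seed = 73)
  panel <- sample_panel(cfg)
  expect_true(all(panel$freq >= 0.01 & panel$freq <= 0.49))
  expect_equal(sum(panel$weights$effect_size > 1), 50)
  expect_true(all(panel$weights$effect_size >= 1.05 - 1e-12 &
                  panel$weights$effect_size <= 1.5 + 1e-12 |
                  panel$weights$effect_size == 1))
  null_panel <- sample_panel(sim_config(n_samples = 100, n_snps = 20,
                                        n_causal = 0, seed = 74))
  expect_true(all(null_panel$weights$effect_size == 1))
})

test_that("observed allele frequencies recover the generating values", {
  cfg <- sim_config(n_samples = 2000, n_snps = 80, missing_rate = 0, seed = 75)
  panel <- sample_panel(cfg)
  G <- simulate_genotypes(panel, cfg)
  obs <- colMeans(G$dosage) / 2
  tol <- 3 * sqrt(panel$freq * (1 - panel$freq) / (2 * cfg$n_samples))
  expect_true(all(abs(obs - panel$freq) <= pmax(tol, 0.015)))
  expect_false(anyNA(G$dosage))   # missing_rate 0 -> complete
})

test_that("simulated genotypes are Hardy-Weinberg compliant at roughly 95%", {
  cfg <- sim_config(n_samples = 1500, n_snps = 150, missing_rate = 0,
                    maf_range = c(0.05, 0.45), seed = 76)
  panel <- sample_panel(cfg)
  G <- simulate_genotypes(panel, cfg)
  pass <- mean(apply(G$dosage, 2, function(x)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))) >= 0.05)
  expect_gt(pass, 0.88)   # exact test is conservative, so above nominal
})

test_that("missingness injection hits the configured rate", {
  cfg <- sim_config(n_samples = 500, n_snps = 100, missing_rate = 0.05, seed = 77)
  panel <- sample_panel(cfg)
  G <- simulate_genotypes(panel, cfg)
  expect_equal(mean(is.na(G$dosage)), 0.05, tolerance = 0.01)
})

test_that("engineered HWE violators are detectably heterozygote-depleted", {
  cfg <- sim_config(n_samples = 700, n_snps = 50, n_hwe_violators = 5,
                    n_ld_duplicates = 0, missing_rate = 0, seed = 78)
  panel <- sample_panel(cfg)
  G <- simulate_genotypes(panel, cfg)
  viol <- inject_qc_violations(G, cfg)
  p_bad <- vapply(viol$truth$hwe, function(id) {
    x <- viol$genotypes$dosage[, id]
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  expect_true(all(p_bad < 0.05))
  # untouched variants keep their dosages
  clean <- viol$truth$clean
  expect_identical(viol$genotypes$dosage[, clean], G$dosage[, clean])
})

test_that("LD duplicates correlate near-perfectly with their sources", {
  cfg <- sim_config(n_samples = 700, n_snps = 50, n_hwe_violators = 0,
                    n_ld_duplicates = 5, missing_rate = 0,
                    maf_range = c(0.1, 0.45), seed = 79)
  panel <- sample_panel(cfg)
  G <- simulate_genotypes(panel, cfg)
  viol <- inject_qc_violations(G, cfg)
  r2 <- mapply(function(dup, src)
    ld_r2(viol$genotypes$dosage[, dup], viol$genotypes$dosage[, src]),
    viol$truth$ld$duplicate, viol$truth$ld$source)
  expect_true(all(r2 > 0.9))
  # zero violations requested leaves the matrix untouched
  cfg0 <- sim_config(n_samples = 100, n_snps = 20, n_hwe_violators = 0,
                     n_ld_duplicates = 0, seed = 80)
  p0 <- sample_panel(cfg0)
  G0 <- simulate_genotypes(p0, cfg0)
  expect_identical(inject_qc_violations(G0, cfg0)$genotypes$dosage, G0$dosage)
})

test_that("liability phenotypes hit configured prevalences and nest comorbidity", {
  cfg <- sim_config(n_samples = 701, n_snps = 150, seed = 81)
  cohort <- simulate_cohort(cfg)
  ph <- cohort$phenotype
  expect_lte(abs(sum(ph$fracture == "case") - 294), 2)
  measured <- !is.na(ph$t_score)
  expect_equal(sum(measured), round(701 * 496 / 701))
  low <- ph$bmd_class %in% c("osteopenia", "osteoporosis")
  expect_equal(mean(low[measured]), 324 / 496, tolerance = 0.02)
  # comorbid cases are exactly the intersection by construction
  com <- make_contrast(ph, "comorbid")
  frac <- make_contrast(ph, "fracture")
  bmd <- make_contrast(ph, "low_bmd")
  expect_true(all(com$case_ids %in% intersect(frac$case_ids, bmd$case_ids)))
  expect_true(all(com$control_ids %in% intersect(frac$control_ids, bmd$control_ids)))
})

test_that("T-score classification respects the WHO boundaries", {
  expect_equal(classify_t_score(c(-3.0, -2.5, -1.7, -1.0, -0.99, 0.5, NA)),
               c("osteoporosis", "osteopenia", "osteopenia", "osteopenia",
                 "normal", "normal", "unknown"))
})

test_that("null heritability gives a scoreless cohort: oracle AUC near 0.5", {
  cfg <- sim_config(n_samples = 4000, n_snps = 60, h2 = 0, missing_rate = 0,
                    n_hwe_violators = 0, n_ld_duplicates = 0, seed = 83)
  cohort <- simulate_cohort(cfg)
  labels <- cohort$phenotype$fracture
  keep <- labels != "unknown"
  auc <- empirical_auc(cohort$truth$model$genetic_value[keep],
                       labels[keep] == "case")
  expect_equal(auc, 0.5, tolerance = 0.03)
})
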