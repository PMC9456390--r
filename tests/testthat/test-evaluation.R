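test_that("Mann-Whitney AUC matches brute-force pair counting", {
  expect_equal(empirical_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(empirical_auc(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(empirical_auc(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  set.seed(61)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    s <- sample(0:5, n, replace = TRUE)          # heavy ties
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(y) || all(y)) next
    expect_equal(empirical_auc(s, y), auc_pair_oracle(s, y), tolerance = 1e-12)
  }
  expect_error(empirical_auc(1:3, c(TRUE, TRUE, TRUE)), "case and one control")
})

test_that("AUC is invariant under monotone transforms and flips under negation", {
  set.seed(62)
  s <- rnorm(80); y <- rep(c(TRUE, FALSE), 40)
  a <- empirical_auc(s, y)
  expect_equal(empirical_auc(exp(s), y), a, tolerance = 1e-12)
  expect_equal(empirical_auc(rank(s), y), a, tolerance = 1e-12)
  expect_equal(empirical_auc(-s, y), 1 - a, tolerance = 1e-12)
})

test_that("ROC curve is monotone with fixed endpoints; trapezoid equals AUC", {
  set.seed(63)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    s <- round(rnorm(n), sample(0:1, 1))         # mix of tied/untied
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(y) || all(y)) next
    roc <- roc_curve(s, y)
    expect_equal(c(roc$tpr[1], roc$fpr[1]), c(0, 0))
    expect_equal(c(roc$tpr[nrow(roc)], roc$fpr[nrow(roc)]), c(1, 1))
    expect_true(all(diff(roc$tpr) >= 0) && all(diff(roc$fpr) >= 0))
    expect_equal(roc_auc_trapezoid(roc), empirical_auc(s, y), tolerance = 1e-12)
  }
})

test_that("Youden point maximizes J with ties broken toward sensitivity", {
  s <- c(10, 9, 8, 3, 2, 1); y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  yp <- youden_operating_point(roc_curve(s, y))
  expect_equal(yp$sensitivity, 1)
  expect_equal(yp$specificity, 1)
  set.seed(64)
  s <- rnorm(100); y <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  roc <- roc_curve(s, y)
  yp <- youden_operating_point(roc)
  expect_true(all(yp$j >= roc$tpr - roc$fpr - 1e-12))
})

test_that("DeLong interval contains the AUC and agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(65)
  s <- rnorm(120); y <- rep(c(TRUE, FALSE), 60)
  s[y] <- s[y] + 1
  a <- empirical_auc(s, y)
  ci <- auc_ci(s, y)
  expect_true(ci[1] <= a && a <= ci[2])
  ref <- suppressMessages(pROC::ci.auc(pROC::roc(y, s, quiet = TRUE),
                                       method = "delong"))
  expect_equal(ci[1], as.numeric(ref[1]), tolerance = 1e-6)
  expect_equal(ci[2], as.numeric(ref[3]), tolerance = 1e-6)
})

test_that("DeLong interval width shrinks with sample size at fixed effect", {
  widths <- vapply(c(100, 1000, 10000), function(n) {
    set.seed(n)
    y <- rep(c(TRUE, FALSE), n / 2)
    s <- rnorm(n) + y
    diff(auc_ci(s, y))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("bootstrap CI is seeded and close to DeLong at moderate n", {
  set.seed(66)
  y <- rep(c(TRUE, FALSE), 150)
  s <- rnorm(300) + 0.8 * y
  b1 <- auc_ci(s, y, method = "bootstrap", n_boot = 500, seed = 9)
  b2 <- auc_ci(s, y, method = "bootstrap", n_boot = 500, seed = 9)
  expect_identical(b1, b2)
  d <- auc_ci(s, y)
  expect_equal(b1, d, tolerance = 0.05)
})

test_that("logistic OR per SD recovers a generative effect and its reciprocal", {
  set.seed(67)
  n <- 5000
  z <- rnorm(n)
  beta <- log(2)
  y <- runif(n) < plogis(-0.3 + beta * z)
  fit <- logistic_or_per_sd(z, y)
  expect_lt(abs(fit$beta - beta), 3 * fit$se)
  flip <- logistic_or_per_sd(-z, y)
  expect_equal(flip$or, 1 / fit$or, tolerance = 1e-6)
})

test_that("separated data falls back to a finite Firth estimate with warning", {
  z <- c(-(5:1), 1:5)
  y <- z > 0
  expect_warning(fit <- logistic_or_per_sd(z, y), "Firth")
  expect_true(is.finite(fit$or) && fit$or > 1)
  expect_true(is.finite(fit$se))
})

test_that("2x2 odds ratio matches the cross-product with symmetry", {
  expect_equal(odds_ratio_2x2(10, 10, 10, 10)$or, 1)
  expect_equal(odds_ratio_2x2(20, 10, 10, 20)$or, 4)
  a <- odds_ratio_2x2(20, 10, 10, 20)
  b <- odds_ratio_2x2(10, 20, 20, 10)
  expect_equal(a$or, 1 / b$or, tolerance = 1e-12)
  # zero cell: Haldane-Anscombe correction keeps the estimate finite
  z <- odds_ratio_2x2(5, 0, 3, 7)
  expect_true(is.finite(z$or) && z$or > 0)
  expect_error(odds_ratio_2x2(0, 0, 3, 7), "empty margin")
})

test_that("decile table splits, accounts, and orders deterministically", {
  set.seed(68)
  s <- rnorm(100); y <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  dt <- decile_table(s, y)
  expect_equal(dt$n, rep(10L, 10))
  expect_equal(sum(dt$n_cases) + sum(dt$n_controls), 100)
  # remainders go to the lower deciles
  dt2 <- decile_table(rnorm(104), sample(c(TRUE, FALSE), 104, replace = TRUE))
  expect_equal(dt2$n, c(rep(11L, 4), rep(10L, 6)))
  # weighted decile case fractions reproduce the overall case fraction
  expect_equal(sum(dt$case_fraction * dt$n) / sum(dt$n), mean(y))
})

test_that("Cochran-Armitage trend test: flat deciles give p = 1, strong trend p < 1e-6", {
  flat <- data.frame(decile = 1:10, n = rep(100L, 10), n_cases = rep(40L, 10),
                     n_controls = rep(60L, 10), case_fraction = 0.4)
  expect_equal(decile_trend_test(flat), 1.0)
  rising <- data.frame(decile = 1:10, n = rep(100L, 10),
                       n_cases = as.integer(seq(5, 95, by = 10)))
  rising$n_controls <- rising$n - rising$n_cases
  rising$case_fraction <- rising$n_cases / rising$n
  expect_lt(decile_trend_test(rising), 1e-6)
})

test_that("group summaries: medians, means, translation equivariance", {
  s <- c(1, 2, 5, 0, 0, 0); y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  gs <- group_summary(s, y)
  expect_equal(gs$median_case, 2)
  expect_equal(gs$median_control, 0)
  s2 <- s; s2[y] <- s2[y] + 1
  expect_equal(group_summary(s2, y)$median_case, 3)
})

test_that("evaluate_contrast assembles a coherent report", {
  set.seed(69)
  n <- 200
  ph <- data.frame(sample_id = sprintf("s%03d", 1:n),
                   fracture = sample(c("case", "control"), n, TRUE),
                   t_score = rnorm(n, -1.5, 1))
  ph$bmd_class <- classify_t_score(ph$t_score)
  z <- rnorm(n) + 0.8 * (ph$fracture == "case")
  ss <- data.frame(sample_id = ph$sample_id, z_prs = z)
  rep1 <- evaluate_contrast(ss, ph, "fracture")
  expect_s3_class(rep1, "eval_report")
  expect_true(rep1$auc_ci[1] <= rep1$auc && rep1$auc <= rep1$auc_ci[2])
  expect_equal(sum(rep1$decile_table$n), rep1$n_cases + rep1$n_controls)
  expect_equal(roc_auc_trapezoid(rep1$roc), rep1$auc, tolerance = 1e-12)
  expect_true(rep1$sensitivity >= 0 && rep1$sensitivity <= 1)
  expect_true(rep1$specificity >= 0 && rep1$specificity <= 1)
  # comorbid contrast excludes discordant samples
  rep2 <- evaluate_contrast(ss, ph, "comorbid")
  expect_lte(rep2$n_cases + rep2$n_controls, n)
})
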