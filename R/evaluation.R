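#' Mann-Whitney (concordance) AUC
#'
#' Probability that a randomly chosen case scores above a randomly chosen
#' control, ties counted one half — the nonparametric area under the ROC
#' curve. Computed from midranks, so it is exact under ties.
#'
#' @param scores numeric vector
#' @param labels logical (TRUE = case) or character `"case"`/`"control"`
#'   vector, same length
#' @return AUC in \[0, 1\]
#' @export
empirical_auc <- function(scores, labels) {
  y <- as_case_logical(labels)
  m <- sum(y); n <- sum(!y)
  if (m == 0 || n == 0) stopf("need at least one case and one control")
  r <- rank(scores)
  (sum(r[y]) - m * (m + 1) / 2) / (m * n)
}

as_case_logical <- function(labels) {
  if (is.logical(labels)) {
    if (anyNA(labels)) stopf("labels contain NA")
    return(labels)
  }
  lab <- as.character(labels)
  bad <- !lab %in% c("case", "control")
  if (any(bad)) stopf("labels must be case/control or logical")
  lab == "case"
}

# DeLong placement values via midranks: V10 per case, V01 per control
delong_components <- function(scores, y) {
  m <- sum(y); n <- sum(!y)
  r_all <- rank(scores)
  r_case <- rank(scores[y])
  r_ctrl <- rank(scores[!y])
  v10 <- (r_all[y] - r_case) / n
  v01 <- 1 - (r_all[!y] - r_ctrl) / m
  list(v10 = v10, v01 = v01, m = m, n = n)
}

#' Confidence interval for the AUC
#'
#' Default method is DeLong's asymptotic variance of the Mann-Whitney
#' statistic with a normal-approximation interval, clipped to \[0, 1\]. A
#' seeded percentile bootstrap over samples is available as an alternative.
#'
#' @inheritParams empirical_auc
#' @param level confidence level (default 0.95)
#' @param method `"delong"` (default) or `"bootstrap"`
#' @param n_boot bootstrap resamples (default 2000)
#' @param seed seed for the bootstrap stream (required for
#'   `method = "bootstrap"`)
#' @return numeric vector `c(lo, hi)`
#' @export
auc_ci <- function(scores, labels, level = 0.95,
                   method = c("delong", "bootstrap"),
                   n_boot = 2000, seed = NULL) {
  method <- match.arg(method)
  y <- as_case_logical(labels)
  auc <- empirical_auc(scores, y)
  if (method == "bootstrap") {
    if (is.null(seed)) stopf("bootstrap CI requires a seed")
    set.seed(seed)
    ic <- which(y); in_ <- which(!y)
    reps <- vapply(seq_len(n_boot), function(i) {
      bi <- sample(ic, replace = TRUE)
      bn <- sample(in_, replace = TRUE)
      empirical_auc(c(scores[bi], scores[bn]),
                    c(rep(TRUE, length(bi)), rep(FALSE, length(bn))))
    }, numeric(1))
    a <- (1 - level) / 2
    return(unname(stats::quantile(reps, c(a, 1 - a))))
  }
  dc <- delong_components(scores, y)
  v <- stats::var(dc$v10) / dc$m + stats::var(dc$v01) / dc$n
  if (!is.finite(v) || v <= 0) {
    warnf("degenerate DeLong variance; returning the widest informative interval")
    return(c(0, 1))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(max(0, auc - z * sqrt(v)), min(1, auc + z * sqrt(v)))
}

#' Stepwise ROC curve
#'
#' Sweeps every distinct score as a threshold (prediction positive when
#' `score >= threshold`), returning the full curve with the (0,0) and (1,1)
#' endpoints. The trapezoidal area under this curve equals the Mann-Whitney
#' AUC, including under ties.
#'
#' @inheritParams empirical_auc
#' @return data frame with columns `threshold`, `tpr`, `fpr`, ordered from
#'   (0,0) to (1,1)
#' @export
roc_curve <- function(scores, labels) {
  y <- as_case_logical(labels)
  if (!any(y) || all(y)) stopf("need at least one case and one control")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  cs <- scores[y]; ct <- scores[!y]
  tpr <- vapply(thr, function(t) mean(cs >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(ct >= t), numeric(1))
  data.frame(threshold = thr, tpr = tpr, fpr = fpr)
}

#' Trapezoidal area under an ROC curve
#' @param roc data frame from [roc_curve()]
#' @return area in \[0, 1\]
#' @export
roc_auc_trapezoid <- function(roc) {
  n <- nrow(roc)
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-n]) / 2)
}

#' Youden-optimal operating point
#'
#' Threshold maximizing Youden's J = sensitivity + specificity - 1; ties are
#' broken toward higher sensitivity.
#'
#' @param roc data frame from [roc_curve()]
#' @return list with `threshold`, `sensitivity`, `specificity`, `j`
#' @export
youden_operating_point <- function(roc) {
  j <- roc$tpr - roc$fpr
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.max(roc$tpr[best])]
  list(threshold = roc$threshold[best],
       sensitivity = roc$tpr[best],
       specificity = 1 - roc$fpr[best],
       j = j[best])
}

#' Odds ratio per standard deviation of the polygenic score
#'
#' Univariable logistic regression of case status on the z-normalized score,
#' by maximum likelihood; the reported odds ratio is `exp(beta)` per 1 SD,
#' with Wald 95% interval and p-value. Complete or quasi-complete separation
#' is detected and handled by refitting with Firth's penalized likelihood
#' (with a warning).
#'
#' @param z_scores z-normalized scores
#' @param labels case/control labels
#' @return list with `or`, `ci_lo`, `ci_hi`, `p`, `beta`, `se`, `method`
#' @export
logistic_or_per_sd <- function(z_scores, labels) {
  y <- as_case_logical(labels)
  if (!any(y) || all(y)) stopf("need both classes")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ z_scores, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)[2]
  if (sep || abs(beta) > 15) {
    warnf("separation detected; reporting Firth penalized-likelihood estimate")
    fl <- firth_logistic(cbind(1, z_scores), as.numeric(y))
    beta <- fl$beta[2]; se <- fl$se[2]; method <- "firth"
  } else {
    se <- sqrt(diag(stats::vcov(fit)))[2]
    method <- "ml"
  }
  z <- beta / se
  list(or = exp(beta),
       ci_lo = exp(beta - 1.959963984540054 * se),
       ci_hi = exp(beta + 1.959963984540054 * se),
       p = 2 * stats::pnorm(-abs(z)),
       beta = unname(beta), se = unname(se), method = method)
}

# Firth bias-reduced logistic regression (Jeffreys-prior penalty); used only
# when ordinary ML separates. Modified-score Newton iterations.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% b)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    h <- rowSums((XW %*% solve(info)) * XW)
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- solve(info, U)
    b <- b + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  list(beta = b, se = sqrt(diag(solve(info))))
}

#' Odds ratio from a 2x2 table
#'
#' Cross-product odds ratio `ad/bc` with the Haldane-Anscombe 0.5 continuity
#' correction applied to every cell when any cell is zero; Woolf logit 95%
#' interval; chi-square p-value (without Yates correction) on the
#' uncorrected counts.
#'
#' @param a,b,c,d counts: `a` exposed cases, `b` exposed controls,
#'   `c` unexposed cases, `d` unexposed controls
#' @return list with `or`, `ci_lo`, `ci_hi`, `p`
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  cts <- c(a, b, c, d)
  if (any(is.na(cts)) || any(cts < 0)) stopf("counts must be non-negative")
  tab <- matrix(cts, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("2x2 table has an empty margin")
  if (any(cts == 0)) cts <- cts + 0.5
  or <- (cts[1] * cts[4]) / (cts[2] * cts[3])
  se <- sqrt(sum(1 / cts))
  z <- stats::qnorm(0.975)
  p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  list(or = or, ci_lo = exp(log(or) - z * se), ci_hi = exp(log(or) + z * se),
       p = p)
}

#' Decile risk table
#'
#' Samples are ranked by score (ties kept in stable order by sample id) and
#' cut into 10 contiguous groups; when the cohort size is not a multiple of
#' 10 the lower deciles take the remainders. Per decile, case and control
#' counts and the case fraction are reported.
#'
#' @inheritParams empirical_auc
#' @param sample_ids optional ids used only to stabilize tie order
#' @return data frame with columns `decile`, `n`, `n_cases`, `n_controls`,
#'   `case_fraction`
#' @export
decile_table <- function(scores, labels, sample_ids = NULL) {
  y <- as_case_logical(labels)
  n <- length(scores)
  if (n < 10) stopf("need at least 10 samples for deciles")
  if (is.null(sample_ids)) sample_ids <- seq_len(n)
  ord <- order(scores, sample_ids)
  sizes <- rep(n %/% 10L, 10L)
  rem <- n %% 10L
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  dec <- rep(1:10, times = sizes)
  yo <- y[ord]
  n_cases <- tapply(yo, dec, sum)
  data.frame(decile = 1:10,
             n = as.integer(sizes),
             n_cases = as.integer(n_cases),
             n_controls = as.integer(sizes - n_cases),
             case_fraction = as.numeric(n_cases / sizes))
}

#' Cochran-Armitage trend test across score deciles
#'
#' Tests for a linear trend in case fraction across deciles scored 1..10.
#'
#' @param dt decile table from [decile_table()]
#' @return p-value
#' @export
decile_trend_test <- function(dt) {
  if (nrow(dt) != 10) stopf("expected 10 deciles")
  if (sum(dt$n_cases) == 0 || sum(dt$n_controls) == 0) return(1.0)
  tt <- suppressWarnings(
    stats::prop.trend.test(dt$n_cases, dt$n, score = 1:10))
  if (!is.finite(tt$statistic) || tt$statistic == 0) return(1.0)
  unname(tt$p.value)
}

#' Per-group score summaries
#'
#' Medians and means per group, plus the raw score vectors, so density plots
#' comparing cases and controls can be redrawn.
#'
#' @inheritParams empirical_auc
#' @return list with `median_case`, `median_control`, `mean_case`,
#'   `mean_control`, `scores_case`, `scores_control`
#' @export
group_summary <- function(scores, labels) {
  y <- as_case_logical(labels)
  if (!any(y) || all(y)) stopf("need both groups non-empty")
  list(median_case = stats::median(scores[y]),
       median_control = stats::median(scores[!y]),
       mean_case = mean(scores[y]),
       mean_control = mean(scores[!y]),
       scores_case = scores[y],
       scores_control = scores[!y])
}

#' Evaluate normalized polygenic scores against one case-control contrast
#'
#' Runs the full evaluation battery for a contrast: Mann-Whitney AUC with
#' confidence interval, ROC curve and Youden operating point, logistic odds
#' ratio per SD (primary) plus a top-versus-bottom-decile 2x2 odds ratio
#' (secondary, since group-contrast odds ratios are also common practice),
#' decile table with Cochran-Armitage trend test, and group score summaries.
#'
#' @param scores a `score_set` from [score_cohort()] (or any data frame with
#'   `sample_id` and `z_prs`)
#' @param phenotype phenotype table
#' @param contrast contrast name passed to [make_contrast()], or a contrast
#'   list built by it
#' @param ci_method `"delong"` or `"bootstrap"` (see [auc_ci()])
#' @param seed seed for bootstrap resampling (only used when
#'   `ci_method = "bootstrap"`)
#' @return an `eval_report` list
#' @export
evaluate_contrast <- function(scores, phenotype, contrast = "fracture",
                              ci_method = c("delong", "bootstrap"),
                              seed = NULL) {
  ci_method <- match.arg(ci_method)
  if (is.character(contrast)) contrast <- make_contrast(phenotype, contrast)
  sel <- scores$sample_id %in% c(contrast$case_ids, contrast$control_ids)
  s <- scores$z_prs[sel]
  ids <- scores$sample_id[sel]
  y <- ids %in% contrast$case_ids

  roc <- roc_curve(s, y)
  yp <- youden_operating_point(roc)
  orr <- logistic_or_per_sd(s, y)
  dt <- decile_table(s, y, sample_ids = ids)
  gs <- group_summary(s, y)
  # secondary group-based OR: top decile vs bottom decile exposure
  top <- dt[10, ]; bot <- dt[1, ]
  or2 <- odds_ratio_2x2(top$n_cases, top$n_controls, bot$n_cases, bot$n_controls)

  structure(list(
    contrast = contrast$name,
    n_cases = sum(y), n_controls = sum(!y),
    auc = empirical_auc(s, y),
    auc_ci = auc_ci(s, y, method = ci_method, seed = seed),
    threshold = yp$threshold,
    sensitivity = yp$sensitivity,
    specificity = yp$specificity,
    or_per_sd = orr,
    or_top_vs_bottom_decile = or2,
    decile_table = dt,
    trend_p = decile_trend_test(dt),
    group_medians = c(case = gs$median_case, control = gs$median_control),
    group_means = c(case = gs$mean_case, control = gs$mean_control),
    scores_case = gs$scores_case,
    scores_control = gs$scores_control,
    roc = roc), class = "eval_report")
}

#' @exportS3Method
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s]: %d cases vs %d controls\n",
              x$contrast, x$n_cases, x$n_controls))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f); sens %.3f, spec %.3f at Youden threshold %.3f\n",
              x$auc, x$auc_ci[1], x$auc_ci[2],
              x$sensitivity, x$specificity, x$threshold))
  cat(sprintf("  OR per SD %.2f (95%% CI %.2f-%.2f), p = %.3g; trend p = %.3g\n",
              x$or_per_sd$or, x$or_per_sd$ci_lo, x$or_per_sd$ci_hi,
              x$or_per_sd$p, x$trend_p))
  invisible(x)
}
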