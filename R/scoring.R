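#' Per-individual polygenic score
#'
#' For sample `j`, the score sums the effect-allele dosages weighted by the
#' per-allele effect sizes and divides by ploidy times the number of
#' non-missing variants:
#' \deqn{PRS_j = \frac{\sum_i s_i G_{ij}}{2 \, M_j}}
#' where `G_ij` is the effect-allele dosage, `s_i = log(OR_i)` under
#' `transform = "log"` (the default: odds ratios multiply, so their logs add
#' on the liability scale) or `s_i = OR_i` under `"identity"`, the sum runs
#' over variants with observed genotypes, and `M_j` counts those variants.
#' Dividing by the non-missing count makes scores comparable between samples
#' with different genotyping success (the average-score convention).
#'
#' @param G a [genotype_matrix()]
#' @param W weight table; its variants must all be present in `G`
#' @param transform `"log"` (default) or `"identity"` weight transform
#' @return a `score_set` data frame with columns `sample_id`, `raw_prs`,
#'   `z_prs` (`NA` until [normalize_scores()] is applied via
#'   [score_cohort()]), `n_used`; attribute `weight_transform`
#' @export
compute_prs <- function(G, W, transform = c("log", "identity")) {
  transform <- match.arg(transform)
  W <- validate_variants(W)
  idx <- match(W$variant_id, G$variants$variant_id)
  if (anyNA(idx))
    stopf("weight-table variant(s) absent from genotypes: %s",
          paste(W$variant_id[is.na(idx)], collapse = ", "))
  d <- G$dosage[, idx, drop = FALSE]
  s <- if (transform == "log") log(W$effect_size) else W$effect_size
  n_used <- rowSums(!is.na(d))
  if (any(n_used == 0))
    stopf("sample(s) with all genotypes missing: %s",
          paste(rownames(d)[n_used == 0], collapse = ", "))
  d0 <- d
  d0[is.na(d0)] <- 0L
  raw <- as.vector(d0 %*% s) / (G$ploidy * n_used)
  structure(data.frame(sample_id = sample_ids(G),
                       raw_prs = raw,
                       z_prs = NA_real_,
                       n_used = n_used,
                       row.names = NULL,
                       stringsAsFactors = FALSE),
            weight_transform = transform,
            class = c("score_set", "data.frame"))
}

#' Z-normalize raw polygenic scores
#'
#' @param raw_prs numeric vector of raw scores (length >= 2)
#' @param center,scale optional externally supplied mean and standard
#'   deviation (e.g. control-only moments); defaults to the vector's own
#'   mean and sample SD (n - 1 denominator)
#' @return numeric vector with mean 0 and SD 1 (under default moments)
#' @export
normalize_scores <- function(raw_prs, center = NULL, scale = NULL) {
  if (length(raw_prs) < 2) stopf("need at least two samples to normalize")
  center <- center %||% mean(raw_prs)
  scale <- scale %||% stats::sd(raw_prs)
  if (!is.finite(scale) || scale == 0)
    stopf("degenerate cohort: score standard deviation is zero")
  (raw_prs - center) / scale
}

#' Percentile ranks of polygenic scores
#'
#' Midpoint-convention percentile rank in \[0, 100\]: the sample with rank
#' `r` of `n` (average rank under ties) gets `(r - 0.5) / n * 100`, so a
#' total tie maps everyone to 50.
#'
#' @param scores numeric vector (typically `raw_prs` or `z_prs`)
#' @return numeric vector of percentile ranks
#' @export
score_percentiles <- function(scores) {
  r <- rank(scores, ties.method = "average")
  (r - 0.5) / length(scores) * 100
}

#' Score a cohort: compute, normalize, and rank polygenic scores
#'
#' Convenience wrapper running [compute_prs()], [normalize_scores()], and
#' [score_percentiles()]. Normalization moments come from the whole cohort by
#' default, or from fracture controls only.
#'
#' @inheritParams compute_prs
#' @param normalize `"cohort"` (default) or `"controls"`; the latter requires
#'   `phenotype`
#' @param phenotype phenotype table identifying controls
#' @return a complete `score_set` with `z_prs` and `percentile` filled in
#' @export
score_cohort <- function(G, W, transform = c("log", "identity"),
                         normalize = c("cohort", "controls"),
                         phenotype = NULL) {
  normalize <- match.arg(normalize)
  ss <- compute_prs(G, W, transform)
  if (normalize == "controls") {
    if (is.null(phenotype)) stopf("control-based normalization needs a phenotype table")
    ph <- validate_phenotypes(phenotype)
    ctrl <- ss$sample_id %in% ph$sample_id[ph$fracture == "control"]
    if (sum(ctrl) < 2) stopf("fewer than two controls available for normalization")
    ss$z_prs <- normalize_scores(ss$raw_prs,
                                 center = mean(ss$raw_prs[ctrl]),
                                 scale = stats::sd(ss$raw_prs[ctrl]))
  } else {
    ss$z_prs <- normalize_scores(ss$raw_prs)
  }
  ss$percentile <- score_percentiles(ss$raw_prs)
  ss
}
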