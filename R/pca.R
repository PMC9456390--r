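#' Standardize a genotype matrix for principal component analysis
#'
#' Per variant, dosages are centered at twice the observed effect-allele
#' frequency and scaled by the binomial standard deviation
#' `sqrt(2 p (1 - p))`; missing entries become exactly 0 after centering
#' (mean imputation). This is the usual normalization for genotype PCA, under
#' which each variant contributes unit variance under Hardy-Weinberg
#' proportions.
#'
#' @param G a [genotype_matrix()]; every variant must be polymorphic
#' @return numeric matrix, samples x variants, column means exactly 0
#' @export
standardize_genotypes <- function(G) {
  d <- G$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  mono <- !is.finite(p) | p <= 0 | p >= 1
  if (any(mono))
    stopf("monomorphic variant(s) %s: run quality control before PCA",
          paste(G$variants$variant_id[mono], collapse = ", "))
  x <- sweep(d, 2, 2 * p)
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0
  x
}

#' Top principal components of a genotype matrix
#'
#' Eigen-decomposition of the sample covariance of the standardized matrix,
#' via singular value decomposition. The sign of each component is fixed so
#' the largest-magnitude variant loading is positive, making scores
#' reproducible across runs and platforms.
#'
#' @param G a [genotype_matrix()]
#' @param k number of components, `k <= min(samples - 1, variants)`
#' @return a `pca_result`: list with `scores` (samples x k, rownames sample
#'   ids), `eigenvalues` (descending), `explained_fraction`
#' @export
compute_pcs <- function(G, k = 2) {
  x <- standardize_genotypes(G)
  n <- nrow(x)
  if (!is_count(k) || k < 1 || k > min(n - 1, ncol(x)))
    stopf("k must be in 1..min(samples - 1, variants)")
  sv <- svd(x, nu = k, nv = k)
  eig <- sv$d^2 / (n - 1)
  total <- sum(eig)
  for (j in seq_len(k)) {
    load <- sv$v[, j]
    if (load[which.max(abs(load))] < 0) {
      sv$v[, j] <- -load
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- sample_ids(G)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 eigenvalues = eig[seq_len(k)],
                 explained_fraction = eig[seq_len(k)] / total),
            class = "pca_result")
}

#' @exportS3Method
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d components (%.1f%% variance)\n",
              nrow(x$scores), ncol(x$scores),
              100 * sum(x$explained_fraction)))
  invisible(x)
}

#' Permutation test for population stratification in the PC plane
#'
#' Quantifies whether samples cluster by group label (e.g. self-reported
#' ethnicity) in the top-two principal-component plane. The statistic is the
#' mean Euclidean distance between group centroids; its null distribution is
#' obtained by shuffling labels. A large p-value supports analysing the
#' cohort as a single population.
#'
#' @param pca a `pca_result` from [compute_pcs()] with at least 2 components
#' @param labels per-sample group labels (length = samples); at least two
#'   groups with two members each
#' @param n_perm number of label permutations (default 999)
#' @param seed integer seed for the permutation stream
#' @return list with `p`, `statistic`, `n_perm`
#' @export
stratification_test <- function(pca, labels, n_perm = 999, seed) {
  if (missing(seed)) stopf("seed is required")
  sc <- pca$scores[, 1:2, drop = FALSE]
  labels <- as.character(labels)
  if (length(labels) != nrow(sc)) stopf("labels must match sample count")
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2))
    stopf("need at least two groups with at least two members each")

  centroid_spread <- function(lab) {
    cx <- tapply(sc[, 1], lab, mean)
    cy <- tapply(sc[, 2], lab, mean)
    pairs <- utils::combn(length(cx), 2)
    mean(sqrt((cx[pairs[1, ]] - cx[pairs[2, ]])^2 +
              (cy[pairs[1, ]] - cy[pairs[2, ]])^2))
  }
  obs <- centroid_spread(labels)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm))
    if (centroid_spread(sample(labels)) >= obs) exceed <- exceed + 1L
  list(p = (exceed + 1) / (n_perm + 1), statistic = obs, n_perm = n_perm)
}
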