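#' Quality-control configuration
#'
#' Thresholds for the locus/sample exclusion step that precedes scoring:
#' per-sample and per-variant genotyping success rates (0.97), the admissible
#' minor-allele-frequency window (1-49%), the Hardy-Weinberg exact-test
#' significance level (0.05), the dosage-r2 ceiling for linkage-disequilibrium
#' pruning (0.8), and the significance level used when screening effect
#' weights for heterogeneity (0.1).
#'
#' @param sample_call_rate_min,variant_call_rate_min minimum non-missing
#'   fraction per sample / per variant
#' @param maf_min,maf_max admissible minor allele frequency window
#' @param hwe_alpha significance level below which a variant is removed by the
#'   Hardy-Weinberg exact test
#' @param ld_r2_max maximum pairwise dosage r2 tolerated between retained
#'   variants on the same chromosome
#' @param heterogeneity_alpha significance level for Cochran's Q when
#'   screening weights (not part of the default filter chain)
#' @param hwe_samples `"controls"` to test Hardy-Weinberg on fracture controls
#'   only (case ascertainment distorts genotype frequencies), `"all"` to use
#'   every sample; falls back to all samples when no phenotype is supplied
#' @return a list of class `qc_config`
#' @export
qc_config <- function(sample_call_rate_min = 0.97,
                      variant_call_rate_min = 0.97,
                      maf_min = 0.01, maf_max = 0.49,
                      hwe_alpha = 0.05,
                      ld_r2_max = 0.8,
                      heterogeneity_alpha = 0.1,
                      hwe_samples = c("controls", "all")) {
  hwe_samples <- match.arg(hwe_samples)
  props <- c(sample_call_rate_min, variant_call_rate_min, maf_min, maf_max,
             hwe_alpha, ld_r2_max, heterogeneity_alpha)
  if (any(props <= 0) || any(props >= 1))
    stopf("all qc_config proportions must lie in (0, 1)")
  if (maf_min >= maf_max) stopf("maf_min must be below maf_max")
  structure(list(sample_call_rate_min = sample_call_rate_min,
                 variant_call_rate_min = variant_call_rate_min,
                 maf_min = maf_min, maf_max = maf_max,
                 hwe_alpha = hwe_alpha, ld_r2_max = ld_r2_max,
                 heterogeneity_alpha = heterogeneity_alpha,
                 hwe_samples = hwe_samples),
            class = "qc_config")
}

#' Minor allele frequency from a dosage vector
#'
#' @param dosages vector of effect-allele dosages in \{0,1,2\}; `NA` entries
#'   are dropped
#' @return `min(p, 1 - p)` where `p` is the effect-allele frequency
#'   `mean(dosage) / 2` over non-missing entries
#' @export
minor_allele_frequency <- function(dosages) {
  dosages <- dosages[!is.na(dosages)]
  if (!length(dosages)) stopf("no non-missing dosages")
  p <- mean(dosages) / 2
  min(p, 1 - p)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, every heterozygote count with
#' the right parity defines one possible genotype table; the two-sided exact
#' p-value sums the conditional probabilities of all tables no more probable
#' than the observed one (standard, non-mid p). Returns 1 when only one table
#' is possible (e.g. a monomorphic variant).
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts
#' @return exact two-sided p-value in (0, 1]
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  cts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(is.na(cts)) || any(cts < 0) || any(cts != floor(cts)))
    stopf("genotype counts must be non-negative integers")
  n <- sum(cts)
  if (n == 0) stopf("at least one genotype required")
  n_a <- 2 * n_hom_ref + n_het          # allele counts; test is symmetric
  n_rare <- min(n_a, 2 * n - n_a)
  h_vals <- seq.int(n_rare %% 2, n_rare, by = 2L)
  if (length(h_vals) == 1L) return(1.0)
  hom_rare <- (n_rare - h_vals) / 2
  hom_common <- n - h_vals - hom_rare
  logw <- h_vals * log(2) - lfactorial(hom_rare) - lfactorial(h_vals) -
    lfactorial(hom_common)
  logw <- logw - max(logw)
  prob <- exp(logw) / sum(exp(logw))
  p_obs <- prob[h_vals == n_het]
  min(1.0, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

#' Pairwise linkage disequilibrium as squared dosage correlation
#'
#' Squared Pearson correlation of two dosage vectors over pairwise-complete
#' entries — the composite-LD (genotype correlation) surrogate for haplotype
#' r2, which needs no phase.
#'
#' @param d1,d2 dosage vectors of equal length
#' @return r2 in \[0, 1\], or `NA` when fewer than two pairwise-complete
#'   entries remain or either variant is monomorphic on the complete subset
#'   (pruning treats `NA` as r2 = 0)
#' @export
ld_r2 <- function(d1, d2) {
  if (length(d1) != length(d2)) stopf("dosage vectors differ in length")
  ok <- !is.na(d1) & !is.na(d2)
  if (sum(ok) < 2) return(NA_real_)
  x <- d1[ok]; y <- d2[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Remove samples and variants with poor genotyping success
#'
#' Samples below the per-sample call-rate threshold are removed first; variant
#' call rates are then computed on the retained samples and failing variants
#' removed.
#'
#' @param G a [genotype_matrix()]
#' @param cfg a [qc_config()]
#' @return list with `genotypes` (filtered matrix), `removed_samples`
#'   (character), `removed_variants` (character)
#' @export
call_rate_filter <- function(G, cfg = qc_config()) {
  d <- G$dosage
  if (!nrow(d) || !ncol(d)) stopf("empty genotype matrix")
  sample_cr <- rowMeans(!is.na(d))
  drop_s <- sample_ids(G)[sample_cr < cfg$sample_call_rate_min]
  if (length(drop_s) == nrow(d)) stopf("all samples fail the call-rate filter")
  keep_s <- !rownames(d) %in% drop_s
  variant_cr <- colMeans(!is.na(d[keep_s, , drop = FALSE]))
  drop_v <- G$variants$variant_id[variant_cr < cfg$variant_call_rate_min]
  keep_v <- !G$variants$variant_id %in% drop_v
  list(genotypes = subset_genotypes(G, samples = keep_s, variants = keep_v),
       removed_samples = drop_s, removed_variants = drop_v)
}

#' Greedy linkage-disequilibrium pruning
#'
#' Per chromosome, variants are visited in map order; each retained variant
#' eliminates later variants whose dosage r2 with it exceeds `ld_r2_max`.
#' Within a conflicting pair the variant with the higher call rate is kept
#' (ties: higher minor allele frequency, then earlier map order).
#'
#' @param G a [genotype_matrix()]
#' @param cfg a [qc_config()]
#' @return list with `genotypes` and `removed_variants`
#' @export
ld_prune <- function(G, cfg = qc_config()) {
  d <- G$dosage
  v <- G$variants
  m <- ncol(d)
  if (m < 2) return(list(genotypes = G, removed_variants = character(0)))
  call_rate <- colMeans(!is.na(d))
  maf <- apply(d, 2, function(x) if (all(is.na(x))) 0 else minor_allele_frequency(x))
  removed <- rep(FALSE, m)
  for (chr in unique(v$chromosome)) {
    idx <- which(v$chromosome == chr)
    idx <- idx[order(v$position[idx])]
    for (a in seq_along(idx)) {
      i <- idx[a]
      if (removed[i]) next
      for (b in seq_along(idx)) {
        if (b <= a) next
        j <- idx[b]
        if (removed[j]) next
        r2 <- ld_r2(d[, i], d[, j])
        if (is.na(r2) || r2 <= cfg$ld_r2_max) next
        # decide which of the conflicting pair survives
        keep_i <- if (call_rate[i] != call_rate[j]) {
          call_rate[i] > call_rate[j]
        } else if (maf[i] != maf[j]) {
          maf[i] > maf[j]
        } else TRUE        # map order: earlier wins
        if (keep_i) removed[j] <- TRUE else { removed[i] <- TRUE; break }
      }
    }
  }
  list(genotypes = subset_genotypes(G, variants = !removed),
       removed_variants = v$variant_id[removed])
}

#' Cochran's Q and I-squared heterogeneity of effect estimates
#'
#' Inverse-variance heterogeneity statistic on the log-odds-ratio scale:
#' `Q = sum(w_i (b_i - b_bar)^2)` with `w_i = 1/se_i^2` and `b_bar` the
#' weighted mean; p from a chi-square with `k - 1` df;
#' `I2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param effects numeric vector of log-odds-ratio estimates (k >= 2)
#' @param std_errors positive standard errors, same length
#' @return list with `Q`, `df`, `p`, `i2` (percent)
#' @export
cochran_q <- function(effects, std_errors) {
  k <- length(effects)
  if (k < 2) stopf("heterogeneity needs at least two effects")
  if (length(std_errors) != k || any(std_errors <= 0))
    stopf("std_errors must be positive and match effects in length")
  w <- 1 / std_errors^2
  b_bar <- sum(w * effects) / sum(w)
  Q <- sum(w * (effects - b_bar)^2)
  df <- k - 1
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE), i2 = i2)
}

#' Run the full locus quality-control chain
#'
#' Filters are applied in a fixed order so every removed variant gets exactly
#' one primary reason: (1) sample call rate, (2) variant call rate, (3) minor
#' allele frequency window, (4) Hardy-Weinberg exact test (on fracture
#' controls when a phenotype table is supplied and `cfg$hwe_samples` is
#' `"controls"`, otherwise on all samples), (5) greedy LD pruning.
#'
#' @param G a [genotype_matrix()]
#' @param cfg a [qc_config()]
#' @param phenotype optional phenotype table used to restrict the
#'   Hardy-Weinberg test to controls
#' @return list with `genotypes` (surviving matrix) and `report`, a
#'   `qc_report` recording counts, removal reasons, and per-variant
#'   call rate / MAF / HWE p statistics
#' @export
run_qc <- function(G, cfg = qc_config(), phenotype = NULL) {
  n_variants_in <- ncol(G$dosage)
  n_samples_in <- nrow(G$dosage)

  cr <- call_rate_filter(G, cfg)
  G1 <- cr$genotypes
  removed <- data.frame(variant_id = cr$removed_variants,
                        reason = rep("call_rate", length(cr$removed_variants)),
                        stringsAsFactors = FALSE)

  d <- G1$dosage
  stats_tab <- data.frame(
    variant_id = G1$variants$variant_id,
    call_rate = colMeans(!is.na(d)),
    maf = apply(d, 2, function(x) if (all(is.na(x))) 0 else minor_allele_frequency(x)),
    hwe_p = NA_real_, stringsAsFactors = FALSE)

  maf_fail <- stats_tab$maf < cfg$maf_min | stats_tab$maf > cfg$maf_max
  removed <- rbind(removed, data.frame(
    variant_id = stats_tab$variant_id[maf_fail],
    reason = rep("maf", sum(maf_fail)), stringsAsFactors = FALSE))
  G2 <- subset_genotypes(G1, variants = !maf_fail)

  hwe_rows <- rep(TRUE, nrow(G2$dosage))
  if (!is.null(phenotype) && cfg$hwe_samples == "controls") {
    ph <- validate_phenotypes(phenotype)
    ctrl <- ph$sample_id[ph$fracture == "control"]
    sel <- sample_ids(G2) %in% ctrl
    if (any(sel)) hwe_rows <- sel
  }
  hwe_p <- apply(G2$dosage[hwe_rows, , drop = FALSE], 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(1.0)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  })
  stats_tab$hwe_p[match(G2$variants$variant_id, stats_tab$variant_id)] <- hwe_p
  hwe_fail <- hwe_p < cfg$hwe_alpha
  removed <- rbind(removed, data.frame(
    variant_id = G2$variants$variant_id[hwe_fail],
    reason = rep("hwe", sum(hwe_fail)), stringsAsFactors = FALSE))
  G3 <- subset_genotypes(G2, variants = !hwe_fail)

  pruned <- ld_prune(G3, cfg)
  removed <- rbind(removed, data.frame(
    variant_id = pruned$removed_variants,
    reason = rep("ld", length(pruned$removed_variants)),
    stringsAsFactors = FALSE))
  G4 <- pruned$genotypes

  if (!ncol(G4$dosage)) stopf("no variants survive quality control")
  report <- structure(list(
    n_variants_in = n_variants_in,
    n_variants_out = ncol(G4$dosage),
    n_samples_in = n_samples_in,
    n_samples_out = nrow(G4$dosage),
    removed_samples = cr$removed_samples,
    removed = removed,
    per_variant_stats = stats_tab), class = "qc_report")
  stopifnot(report$n_variants_out + nrow(removed) == n_variants_in)
  list(genotypes = G4, report = report)
}

#' @exportS3Method
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d/%d variants retained, %d/%d samples retained\n",
              x$n_variants_out, x$n_variants_in,
              x$n_samples_out, x$n_samples_in))
  if (nrow(x$removed))
    print(table(x$removed$reason))
  invisible(x)
}
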