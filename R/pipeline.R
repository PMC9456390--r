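#' Pipeline configuration
#'
#' Either a simulation config (`sim`) or real-input paths (`genotypes` as
#' PED/MAP or VCF, `weights`, `phenotypes`) must be given, not both. The
#' remaining fields control quality control, PCA, scoring, and evaluation.
#'
#' @param sim a [sim_config()], or `NULL` when reading real inputs
#' @param ped_path,map_path,vcf_path genotype input paths (PED/MAP pair, or
#'   a VCF)
#' @param weights_path,phenotype_path weight-table and phenotype TSV paths
#' @param qc a [qc_config()]
#' @param pca_k number of principal components (default 2)
#' @param pca_perms permutations for the stratification test (default 999)
#' @param contrasts contrast names to evaluate (default all three)
#' @param weight_transform `"log"` or `"identity"` (see [compute_prs()])
#' @param normalize `"cohort"` or `"controls"` (see [score_cohort()])
#' @param ci_method `"delong"` or `"bootstrap"` (see [auc_ci()])
#' @param seed integer seed; mandatory
#' @param out_dir optional directory for JSON/TSV outputs
#' @return a list of class `pipeline_config`
#' @export
pipeline_config <- function(sim = NULL,
                            ped_path = NULL, map_path = NULL, vcf_path = NULL,
                            weights_path = NULL, phenotype_path = NULL,
                            qc = qc_config(), pca_k = 2, pca_perms = 999,
                            contrasts = c("fracture", "low_bmd", "comorbid"),
                            weight_transform = c("log", "identity"),
                            normalize = c("cohort", "controls"),
                            ci_method = c("delong", "bootstrap"),
                            seed, out_dir = NULL) {
  if (missing(seed) || !is_count(seed)) stopf("an integer seed is required")
  have_paths <- !is.null(ped_path) || !is.null(vcf_path)
  if (is.null(sim) && !have_paths)
    stopf("either a sim_config or genotype input paths must be given")
  if (!is.null(sim) && have_paths)
    stopf("give either a sim_config or input paths, not both")
  if (!is.null(sim) && !inherits(sim, "sim_config")) stopf("sim must be a sim_config")
  if (!length(contrasts)) stopf("at least one contrast must be requested")
  bad <- setdiff(contrasts, c("fracture", "low_bmd", "comorbid"))
  if (length(bad)) stopf("unknown contrast(s): %s", paste(bad, collapse = ", "))
  structure(list(sim = sim, ped_path = ped_path, map_path = map_path,
                 vcf_path = vcf_path, weights_path = weights_path,
                 phenotype_path = phenotype_path, qc = qc,
                 pca_k = pca_k, pca_perms = pca_perms, contrasts = contrasts,
                 weight_transform = match.arg(weight_transform),
                 normalize = match.arg(normalize),
                 ci_method = match.arg(ci_method),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the five-step polygenic-score pipeline
#'
#' Executes, in fixed order: (1) input loading or cohort simulation,
#' (2) quality control (call rate, MAF, Hardy-Weinberg, LD pruning),
#' (3) PCA with a permutation test for stratification by ethnicity label,
#' (4) polygenic-score computation and normalization, and (5) evaluation of
#' every requested case-control contrast, ranked by AUC; the top-ranked
#' contrast is flagged as the most sensitive and specific model. A manifest
#' records the seed, a configuration fingerprint, and per-stage record
#' counts, and is byte-identical across runs with the same configuration.
#'
#' @param cfg a [pipeline_config()]
#' @return list with `manifest`, `qc_report`, `pca`, `stratification`,
#'   `scores`, `reports` (named list of `eval_report`s), `ranking` (from
#'   [compare_contrasts()] when 2+ contrasts), and `best_contrast`
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) stopf("cfg must be a pipeline_config")

  # stage 1: inputs
  if (!is.null(cfg$sim)) {
    cohort <- simulate_cohort(cfg$sim)
    G <- cohort$genotypes
    weights <- cohort$weights
    phenotype <- cohort$phenotype
  } else {
    weights <- read_weight_table(cfg$weights_path)
    G <- if (!is.null(cfg$vcf_path)) read_vcf(cfg$vcf_path, weights)
         else read_plink_text(cfg$ped_path, cfg$map_path, weights)
    phenotype <- read_phenotype_table(cfg$phenotype_path)
  }
  n_samples_in <- nrow(G$dosage)
  n_variants_in <- ncol(G$dosage)

  # stage 2: quality control
  qc_res <- run_qc(G, cfg$qc, phenotype = phenotype)
  Gq <- qc_res$genotypes

  # stage 3: population-structure check
  pca <- compute_pcs(Gq, k = cfg$pca_k)
  strat <- NULL
  eth <- phenotype$ethnicity[match(sample_ids(Gq), phenotype$sample_id)]
  if (!all(is.na(eth)) && length(unique(eth)) >= 2 && min(table(eth)) >= 2)
    strat <- stratification_test(pca, eth, n_perm = cfg$pca_perms,
                                 seed = derive_seed(cfg$seed, 11))

  # stage 4: scoring and normalization
  w_used <- weights[weights$variant_id %in% Gq$variants$variant_id, ,
                    drop = FALSE]
  scores <- score_cohort(Gq, w_used, transform = cfg$weight_transform,
                         normalize = cfg$normalize, phenotype = phenotype)

  # stage 5: evaluation per contrast
  reports <- list()
  for (ct in cfg$contrasts)
    reports[[ct]] <- evaluate_contrast(scores, phenotype, contrast = ct,
                                       ci_method = cfg$ci_method,
                                       seed = derive_seed(cfg$seed, 12))
  ranking <- if (length(reports) >= 2) compare_contrasts(reports) else NULL
  best <- if (!is.null(ranking)) ranking$contrast[1]
          else reports[[1]]$contrast

  manifest <- list(
    package = "osteopgs",
    seed = cfg$seed,
    config_fingerprint = config_fingerprint(cfg[setdiff(names(cfg), "out_dir")]),
    stages = list(
      input = list(n_samples = n_samples_in, n_variants = n_variants_in),
      qc = list(n_samples = qc_res$report$n_samples_out,
                n_variants = qc_res$report$n_variants_out,
                removed = as.list(table(qc_res$report$removed$reason))),
      pca = list(k = cfg$pca_k,
                 stratification_p = if (is.null(strat)) NA else strat$p),
      scoring = list(n_scored = nrow(scores),
                     weight_transform = cfg$weight_transform,
                     n_weights = nrow(w_used)),
      evaluation = lapply(reports, function(r)
        list(n_cases = r$n_cases, n_controls = r$n_controls, auc = r$auc))),
    best_contrast = best)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    for (ct in names(reports))
      write_eval_report(reports[[ct]],
                        file.path(cfg$out_dir, paste0("report_", ct, ".json")))
    utils::write.table(
      data.frame(sample_id = sample_ids(Gq), pca$scores,
                 label = eth, check.names = FALSE),
      file.path(cfg$out_dir, "pca_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(scores, file.path(cfg$out_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(manifest = manifest, qc_report = qc_res$report, genotypes = Gq,
       pca = pca, stratification = strat, scores = scores,
       reports = reports, ranking = ranking, best_contrast = best)
}

#' Rank evaluated contrasts by AUC
#'
#' @param reports list of two or more `eval_report`s
#' @return data frame ranked by descending AUC with columns `contrast`,
#'   `auc`, `auc_lo`, `auc_hi`, `sensitivity`, `specificity`, `or_per_sd`,
#'   `p`, `p_bonferroni`, `rank` (ties share a rank), and `ci_overlaps_next`
#'   (`TRUE` when the confidence interval overlaps the next-ranked model's,
#'   in which case no superiority claim is warranted)
#' @export
compare_contrasts <- function(reports) {
  if (length(reports) < 2) stopf("need at least two reports to compare")
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(contrast = r$contrast, auc = r$auc,
               auc_lo = r$auc_ci[1], auc_hi = r$auc_ci[2],
               sensitivity = r$sensitivity, specificity = r$specificity,
               or_per_sd = r$or_per_sd$or, p = r$or_per_sd$p,
               stringsAsFactors = FALSE)))
  tab <- tab[order(-tab$auc, tab$contrast), ]
  tab$p_bonferroni <- pmin(1, tab$p * nrow(tab))
  tab$rank <- rank(-tab$auc, ties.method = "min")
  k <- nrow(tab)
  tab$ci_overlaps_next <- c(tab$auc_lo[-k] <= tab$auc_hi[-1], NA)
  rownames(tab) <- NULL
  tab
}
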