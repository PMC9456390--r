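#' Simulation configuration for a synthetic osteoporosis cohort
#'
#' Defaults emulate the study design the pipeline targets: 701 postmenopausal
#' women genotyped at a 150-SNP panel with minor allele frequencies between
#' 1% and 49%, of which ~140 loci survive quality control (5 engineered
#' Hardy-Weinberg violators plus 5 linkage-disequilibrium duplicates emulate
#' the excluded loci); fracture prevalence 294/701, low-BMD prevalence
#' 324/496 among the ~71% of women with a BMD measurement.
#'
#' @param n_samples cohort size (default 701)
#' @param n_snps panel size before quality control (default 150)
#' @param maf_range minor-allele-frequency window for simulated panel
#'   frequencies (default `c(0.01, 0.49)`)
#' @param n_causal number of variants given non-null odds ratios (default:
#'   all of them, emulating a curated risk panel)
#' @param or_range odds-ratio range for causal variants, sampled
#'   log-uniformly (default `c(1.05, 1.5)`, conventional for BMD-associated
#'   common variants)
#' @param prevalence named vector with elements `fracture` and `low_bmd`:
#'   case fractions for the two primary traits (defaults 294/701 and 324/496)
#' @param bmd_measured_fraction fraction of samples with a BMD T-score
#'   (default 496/701)
#' @param h2 liability-scale variance fraction explained by the panel
#'   (default 0.35, giving study-scale discrimination)
#' @param trait_cor total liability correlation between the fracture and BMD
#'   traits (default 0.6)
#' @param missing_rate completely-at-random genotype missingness (default
#'   0.005)
#' @param n_hwe_violators variants whose genotypes are replaced with
#'   heterozygote-depleted draws, inbreeding coefficient F = 0.5 (default 5)
#' @param n_ld_duplicates variants overwritten with a near-copy (1% of
#'   entries re-drawn) of another variant (default 5)
#' @param fst Balding-Nichols differentiation between two equal-size
#'   subpopulations; 0 (default) simulates a single homogeneous population
#' @param seed integer seed; mandatory, drives every stochastic step
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_samples = 701, n_snps = 150,
                       maf_range = c(0.01, 0.49),
                       n_causal = n_snps,
                       or_range = c(1.05, 1.5),
                       prevalence = c(fracture = 294 / 701,
                                      low_bmd = 324 / 496),
                       bmd_measured_fraction = 496 / 701,
                       h2 = 0.35, trait_cor = 0.6,
                       missing_rate = 0.005,
                       n_hwe_violators = 5, n_ld_duplicates = 5,
                       fst = 0, seed) {
  if (missing(seed) || !is_count(seed)) stopf("an integer seed is required")
  if (!is_count(n_samples) || n_samples < 2) stopf("invalid n_samples")
  if (!is_count(n_snps) || n_snps < 1) stopf("invalid n_snps")
  if (n_causal > n_snps) stopf("n_causal cannot exceed n_snps")
  if (n_hwe_violators + n_ld_duplicates > n_snps)
    stopf("engineered violations exceed panel size")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must be in [0, 1)")
  if (fst < 0 || fst >= 1) stopf("fst must be in [0, 1)")
  if (h2 < 0 || h2 >= 1) stopf("h2 must be in [0, 1)")
  if (any(prevalence <= 0) || any(prevalence >= 1))
    stopf("prevalences must be in (0, 1)")
  structure(list(n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps),
                 maf_range = maf_range, n_causal = as.integer(n_causal),
                 or_range = or_range, prevalence = prevalence,
                 bmd_measured_fraction = bmd_measured_fraction,
                 h2 = h2, trait_cor = trait_cor,
                 missing_rate = missing_rate,
                 n_hwe_violators = as.integer(n_hwe_violators),
                 n_ld_duplicates = as.integer(n_ld_duplicates),
                 fst = fst, seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample a variant panel with effect sizes
#'
#' Draws `n_snps` biallelic variants with effect-allele frequencies uniform
#' in `maf_range`, spread across chromosomes 1-22 in map order. A random
#' subset of `n_causal` variants receives odds ratios drawn log-uniformly in
#' `or_range`; the rest get OR = 1.
#'
#' @param cfg a [sim_config()]
#' @return list with `weights` (validated weight table), `freq`
#'   (effect-allele frequencies), `beta` (log odds ratios), `causal`
#'   (variant ids)
#' @export
sample_panel <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 1))
  m <- cfg$n_snps
  freq <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  alleles <- c("A", "C", "G", "T")
  eff <- sample(alleles, m, replace = TRUE)
  oth <- vapply(eff, function(a) sample(setdiff(alleles, a), 1), character(1))
  chrom <- as.character(sort(rep_len(1:22, m)))
  pos <- integer(m)
  for (c in unique(chrom)) {
    i <- which(chrom == c)
    pos[i] <- sort(sample.int(5e7, length(i)))
  }
  or <- rep(1, m)
  causal <- sort(sample.int(m, cfg$n_causal))
  or[causal] <- exp(stats::runif(cfg$n_causal,
                                 log(cfg$or_range[1]), log(cfg$or_range[2])))
  weights <- validate_variants(data.frame(
    variant_id = sprintf("snp%03d", seq_len(m)),
    chromosome = chrom, position = pos,
    effect_allele = eff, other_allele = oth,
    effect_size = or, stringsAsFactors = FALSE))
  list(weights = weights, freq = freq, beta = log(or),
       causal = weights$variant_id[causal])
}

#' Simulate genotypes for a panel
#'
#' Single-population mode draws dosages Binomial(2, p) per variant
#' (Hardy-Weinberg proportions). With `fst > 0`, two equal subpopulations get
#' variant frequencies drawn from the Balding-Nichols Beta distribution
#' around each ancestral frequency. Missingness is then injected completely
#' at random at `missing_rate`.
#'
#' @param panel output of [sample_panel()]
#' @param cfg a [sim_config()]
#' @return a [genotype_matrix()]; attribute `subpop` carries the
#'   subpopulation labels (all `"pop1"` when `fst = 0`)
#' @export
simulate_genotypes <- function(panel, cfg) {
  set.seed(derive_seed(cfg$seed, 2))
  n <- cfg$n_samples
  m <- cfg$n_snps
  dosage <- matrix(NA_integer_, n, m)
  if (cfg$fst > 0) {
    subpop <- rep(c("pop1", "pop2"), length.out = n)
    a <- (1 - cfg$fst) / cfg$fst
    for (j in seq_len(m)) {
      p <- panel$freq[j]
      pk <- stats::rbeta(2, p * a, (1 - p) * a)
      dosage[, j] <- stats::rbinom(n, 2, pk[(subpop == "pop2") + 1L])
    }
  } else {
    subpop <- rep("pop1", n)
    for (j in seq_len(m))
      dosage[, j] <- stats::rbinom(n, 2, panel$freq[j])
  }
  G <- genotype_matrix(dosage, panel$weights,
                       sample_ids = sprintf("I%04d", seq_len(n)))
  if (cfg$missing_rate > 0)
    G <- inject_missingness(G, cfg$missing_rate, derive_seed(cfg$seed, 3))
  attr(G, "subpop") <- subpop
  G
}

#' Inject completely-at-random missingness
#' @param G a [genotype_matrix()]
#' @param rate per-entry missingness probability
#' @param seed integer seed
#' @return a [genotype_matrix()] with entries masked
#' @export
inject_missingness <- function(G, rate, seed) {
  set.seed(seed)
  d <- G$dosage
  mask <- matrix(stats::runif(length(d)) < rate, nrow(d))
  d[mask] <- NA_integer_
  out <- genotype_matrix(d, G$variants)
  attr(out, "subpop") <- attr(G, "subpop")
  out
}

#' Engineer quality-control violations into a genotype matrix
#'
#' Hardy-Weinberg violators are created by replacing a variant's genotypes
#' with draws from an inbreeding-distorted distribution (F = 0.5: genotype
#' probabilities `p^2 + F p q`, `2 p q (1 - F)`, `q^2 + F p q`), which
#' depletes heterozygotes while preserving the allele frequency. LD
#' duplicates are created by overwriting a variant with a copy of another
#' (clean, later-in-map source is the earlier variant) in which 1% of
#' entries are re-drawn from Binomial(2, p).
#'
#' @param G a [genotype_matrix()] (ideally before missingness injection)
#' @param cfg a [sim_config()]; uses `n_hwe_violators` and `n_ld_duplicates`
#' @return list with `genotypes` and `truth`, a list with `hwe` (violator
#'   ids), `ld` (data frame `duplicate`, `source`), `clean` (untouched ids)
#' @export
inject_qc_violations <- function(G, cfg) {
  set.seed(derive_seed(cfg$seed, 4))
  d <- G$dosage
  v <- G$variants
  m <- ncol(d); n <- nrow(d)
  n_bad <- cfg$n_hwe_violators + cfg$n_ld_duplicates
  truth <- list(hwe = character(0),
                ld = data.frame(duplicate = character(0), source = character(0),
                                stringsAsFactors = FALSE),
                clean = v$variant_id)
  if (n_bad == 0)
    return(list(genotypes = G, truth = truth))
  targets <- sample.int(m, n_bad)
  hwe_idx <- targets[seq_len(cfg$n_hwe_violators)]
  ld_idx <- setdiff(targets, hwe_idx)
  for (j in hwe_idx) {
    p <- mean(d[, j], na.rm = TRUE) / 2
    q <- 1 - p
    f <- 0.5
    probs <- c(q^2 + f * p * q, 2 * p * q * (1 - f), p^2 + f * p * q)
    d[, j] <- sample(0:2, n, replace = TRUE, prob = probs)
  }
  src <- character(0)
  used_src <- integer(0)
  for (j in ld_idx) {
    pool <- setdiff(seq_len(m), c(targets, used_src))
    # prefer a same-chromosome source so the duplicate pair is prunable;
    # sources are distinct so pairs never chain through a shared variant
    same <- pool[v$chromosome[pool] == v$chromosome[j]]
    s <- if (length(same)) sample(same, 1) else sample(pool, 1)
    used_src <- c(used_src, s)
    d[, j] <- d[, s]
    flip <- which(stats::runif(n) < 0.01)
    if (length(flip)) {
      p <- mean(d[, s], na.rm = TRUE) / 2
      d[flip, j] <- stats::rbinom(length(flip), 2, p)
    }
    src <- c(src, v$variant_id[s])
  }
  truth$hwe <- v$variant_id[hwe_idx]
  truth$ld <- data.frame(duplicate = v$variant_id[ld_idx], source = src,
                         stringsAsFactors = FALSE)
  truth$clean <- setdiff(v$variant_id, c(truth$hwe, truth$ld$duplicate))
  out <- genotype_matrix(d, v)
  attr(out, "subpop") <- attr(G, "subpop")
  list(genotypes = out, truth = truth)
}

#' True generative model for a simulated cohort
#'
#' Computes per-sample genetic values `g = sum(beta_i * dosage_i)` from
#' complete dosages and the panel's log odds ratios.
#' @param G a [genotype_matrix()] without missingness
#' @param panel output of [sample_panel()]
#' @return list of class `true_model` with `beta`, `genetic_value`
#' @export
true_model <- function(G, panel) {
  d <- G$dosage
  d[is.na(d)] <- 0L
  structure(list(beta = panel$beta,
                 genetic_value = as.vector(d %*% panel$beta),
                 sample_ids = sample_ids(G)),
            class = "true_model")
}

#' Liability-threshold phenotypes for a simulated cohort
#'
#' Each trait's liability is the shared genetic value plus Gaussian
#' environmental noise scaled so the genetic fraction of liability variance
#' equals `h2`; the fracture and BMD environmental terms are correlated so
#' the total cross-trait liability correlation equals `trait_cor`. Cases are
#' samples above the empirical liability quantile implied by each trait's
#' prevalence. BMD liabilities are mapped to T-scores (higher liability =
#' lower BMD) anchored so the low-BMD prevalence sits at the WHO threshold
#' T = -1.0, and classified by [classify_t_score()]; only a random
#' `bmd_measured_fraction` of samples receive a T-score, the rest are
#' `unknown`. With `h2 = 0` liabilities are pure noise.
#'
#' @param G a [genotype_matrix()] (complete dosages preferred)
#' @param model a [true_model()]
#' @param cfg a [sim_config()]
#' @return list with `phenotype` (validated phenotype table) and `truth`
#'   (liabilities and thresholds)
#' @export
liability_phenotypes <- function(G, model, cfg) {
  set.seed(derive_seed(cfg$seed, 5))
  n <- nrow(G$dosage)
  g <- model$genetic_value
  var_g <- stats::var(g)
  if (cfg$h2 > 0 && var_g <= 0)
    stopf("degenerate environmental variance: no genetic variation but h2 > 0")
  if (cfg$h2 == 0) {
    g_used <- rep(0, n)
    sigma_e <- 1
  } else {
    g_used <- g
    sigma_e <- sqrt(var_g * (1 - cfg$h2) / cfg$h2)
  }
  rho_e <- (cfg$trait_cor - cfg$h2) / (1 - cfg$h2)
  rho_e <- min(max(rho_e, 0), 0.999)
  e1 <- stats::rnorm(n)
  e2 <- rho_e * e1 + sqrt(1 - rho_e^2) * stats::rnorm(n)
  liab_frac <- g_used + sigma_e * e1
  liab_bmd <- g_used + sigma_e * e2

  thr_frac <- stats::quantile(liab_frac, 1 - cfg$prevalence[["fracture"]],
                              names = FALSE)
  fracture <- ifelse(liab_frac > thr_frac, "case", "control")

  measured <- sort(sample.int(n, round(n * cfg$bmd_measured_fraction)))
  zb <- (liab_bmd - mean(liab_bmd[measured])) / stats::sd(liab_bmd[measured])
  z_thr <- stats::quantile(zb[measured], 1 - cfg$prevalence[["low_bmd"]],
                           names = FALSE)
  t_score <- rep(NA_real_, n)
  t_score[measured] <- -1.0 - (zb[measured] - z_thr)

  phen <- validate_phenotypes(data.frame(
    sample_id = sample_ids(G),
    fracture = fracture,
    t_score = round(t_score, 6),
    bmd_class = classify_t_score(round(t_score, 6)),
    ethnicity = if (!is.null(attr(G, "subpop")) && cfg$fst > 0)
      attr(G, "subpop") else sample(c("tatar", "russian"), n, replace = TRUE),
    age_years = round(stats::rnorm(n, 61.95, 7.94), 1),
    bmi = round(stats::rnorm(n, 27.5, 3.7), 1),
    stringsAsFactors = FALSE))
  list(phenotype = phen,
       truth = list(liability_fracture = liab_frac,
                    liability_bmd = liab_bmd,
                    threshold_fracture = thr_frac,
                    threshold_bmd_z = z_thr,
                    measured = sample_ids(G)[measured]))
}

#' Oracle AUC from true genetic values
#'
#' The Mann-Whitney AUC computed directly on the latent genetic values of the
#' generative model — the reference the scored pipeline should approach when
#' scoring weights equal the true effect sizes.
#'
#' @param model a [true_model()]
#' @param labels case/control labels in `model$sample_ids` order
#' @return AUC in \[0, 1\]
#' @export
oracle_auc <- function(model, labels) {
  empirical_auc(model$genetic_value, labels)
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates panel sampling, genotype simulation, phenotype generation
#' (from complete genotypes), engineered quality-control violations, and
#' missingness injection, all deterministically from `cfg$seed`.
#'
#' @param cfg a [sim_config()]
#' @return list with `genotypes` (post-violation, post-missingness),
#'   `weights`, `phenotype`, and `truth` (model, liabilities, violation
#'   labels, subpopulation labels)
#' @export
simulate_cohort <- function(cfg) {
  panel <- sample_panel(cfg)
  cfg_complete <- cfg
  cfg_complete$missing_rate <- 0
  G0 <- simulate_genotypes(panel, cfg_complete)
  model <- true_model(G0, panel)
  ph <- liability_phenotypes(G0, model, cfg)
  viol <- inject_qc_violations(G0, cfg)
  G <- viol$genotypes
  if (cfg$missing_rate > 0)
    G <- inject_missingness(G, cfg$missing_rate, derive_seed(cfg$seed, 3))
  list(genotypes = G,
       weights = panel$weights,
       phenotype = ph$phenotype,
       truth = list(model = model, panel = panel,
                    liabilities = ph$truth,
                    violations = viol$truth,
                    subpop = attr(G0, "subpop")))
}
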