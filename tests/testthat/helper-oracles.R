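# Independent oracles used across tests. These deliberately avoid the code
# paths they check: plain factorials and explicit pair loops at small n.

# Exact Hardy-Weinberg p by direct enumeration of heterozygote counts,
# using plain factorial() (valid for totals <= 85).
hwe_enum_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_a <- 2 * n_hom_ref + n_het
  n_rare <- min(n_a, 2 * n - n_a)
  h_vals <- seq.int(n_rare %% 2, n_rare, by = 2L)
  if (length(h_vals) == 1L) return(1.0)
  w <- vapply(h_vals, function(h) {
    hr <- (n_rare - h) / 2
    hc <- n - h - hr
    2^h * factorial(n) / (factorial(hr) * factorial(h) * factorial(hc))
  }, numeric(1))
  prob <- w / sum(w)
  p_obs <- prob[h_vals == n_het]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

# Mann-Whitney AUC by brute force over all (case, control) pairs.
auc_pair_oracle <- function(scores, y) {
  cs <- scores[y]; ct <- scores[!y]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(cs) * length(ct))
}

# tiny deterministic genotype fixture: n samples x m variants
toy_genotypes <- function(dosage, chrom = NULL, or = NULL) {
  m <- ncol(dosage)
  genotype_matrix(dosage, data.frame(
    variant_id = paste0("v", seq_len(m)),
    chromosome = chrom %||% rep("1", m),
    position = seq_len(m) * 1000L,
    effect_allele = rep("A", m),
    other_allele = rep("G", m),
    effect_size = or %||% rep(1.2, m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# drop monomorphic variants (what QC would do) before PCA on raw simulations
drop_monomorphic <- function(G) {
  poly <- apply(G$dosage, 2, function(x) {
    x <- x[!is.na(x)]
    length(unique(x)) > 1
  })
  out <- subset_genotypes(G, variants = poly)
  attr(out, "subpop") <- attr(G, "subpop")
  out
}
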