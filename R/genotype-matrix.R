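#' Genotype matrix container
#'
#' Holds a samples x variants table of effect-allele dosages together with
#' the variant annotations (id, position, allele pair, effect size). Dosage
#' values are integers in \{0, 1, 2\} counting copies of the effect allele;
#' missing genotypes are `NA` so they can never leak into arithmetic
#' (the per-sample denominator of the polygenic score counts non-missing
#' entries explicitly).
#'
#' @param dosage integer matrix, samples in rows, variants in columns,
#'   entries in \{0, 1, 2\} or `NA`. Row names are sample ids, column names
#'   variant ids (supplied via `sample_ids` if absent).
#' @param variants data frame with columns `variant_id`, `chromosome`,
#'   `position`, `effect_allele`, `other_allele`, `effect_size`, one row per
#'   dosage column, in column order.
#' @param sample_ids optional character vector of row ids.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `variants`, and `ploidy` (always 2).
#' @export
genotype_matrix <- function(dosage, variants, sample_ids = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (!is.null(sample_ids)) rownames(dosage) <- sample_ids
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  variants <- validate_variants(variants)
  if (nrow(variants) != ncol(dosage))
    stopf("variant table has %d rows but dosage has %d columns",
          nrow(variants), ncol(dosage))
  colnames(dosage) <- variants$variant_id
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stopf("dosage entries must be in {0, 1, 2} or NA")
  if (anyDuplicated(rownames(dosage)))
    stopf("sample ids must be unique")
  structure(list(dosage = dosage, variants = variants, ploidy = 2L),
            class = "genotype_matrix")
}

validate_variants <- function(variants) {
  need <- c("variant_id", "chromosome", "position",
            "effect_allele", "other_allele", "effect_size")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stopf("variant table missing column(s): %s", paste(miss, collapse = ", "))
  variants <- as.data.frame(variants)[, need]
  variants$variant_id <- as.character(variants$variant_id)
  variants$chromosome <- as.character(variants$chromosome)
  variants$position <- as.integer(variants$position)
  variants$effect_allele <- toupper(as.character(variants$effect_allele))
  variants$other_allele <- toupper(as.character(variants$other_allele))
  if (anyDuplicated(variants$variant_id))
    stopf("duplicate variant_id: %s",
          paste(unique(variants$variant_id[duplicated(variants$variant_id)]),
                collapse = ", "))
  if (any(variants$position < 1L, na.rm = TRUE))
    stopf("positions must be >= 1 (1-based coordinates)")
  if (any(nchar(variants$effect_allele) != 1L) ||
      any(nchar(variants$other_allele) != 1L))
    stopf("alleles must be single characters")
  same <- variants$effect_allele == variants$other_allele
  if (any(same))
    stopf("effect and other allele identical for: %s",
          paste(variants$variant_id[same], collapse = ", "))
  if (any(!is.finite(variants$effect_size)) || any(variants$effect_size <= 0))
    stopf("effect sizes (odds ratios) must be positive and finite")
  rownames(variants) <- NULL
  variants
}

#' @exportS3Method
print.genotype_matrix <- function(x, ...) {
  d <- x$dosage
  cat(sprintf("genotype_matrix: %d samples x %d variants (%.2f%% missing)\n",
              nrow(d), ncol(d), 100 * mean(is.na(d))))
  invisible(x)
}

#' @exportS3Method
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Sample ids of a genotype matrix
#' @param G a `genotype_matrix`
#' @return character vector of sample ids
#' @export
sample_ids <- function(G) rownames(G$dosage)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param G a `genotype_matrix`
#' @param samples row selector (indices, logical, or sample ids)
#' @param variants column selector (indices, logical, or variant ids)
#' @return a `genotype_matrix`
#' @export
subset_genotypes <- function(G, samples = NULL, variants = NULL) {
  d <- G$dosage
  v <- G$variants
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(variants)) {
    if (is.character(variants)) variants <- match(variants, v$variant_id)
    d <- d[, variants, drop = FALSE]
    v <- v[variants, , drop = FALSE]
  }
  genotype_matrix(d, v)
}
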