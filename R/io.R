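#' Read a tab-delimited variant weight table
#'
#' The weight table supplies, for each panel variant, its genomic location,
#' the effect (risk) allele, the other allele, and the per-allele effect size
#' expressed as an odds ratio from prior association studies. Expected header:
#' `variant_id`, `chr`, `pos`, `effect_allele`, `other_allele`, `OR`.
#'
#' @param path path to a TSV file
#' @return data frame with columns `variant_id`, `chromosome`, `position`,
#'   `effect_allele`, `other_allele`, `effect_size`, validated (positive odds
#'   ratios, distinct alleles, unique ids).
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path)) stopf("weight table not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("variant_id", "chr", "pos", "effect_allele", "other_allele", "OR")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("weight table missing column(s): %s", paste(miss, collapse = ", "))
  validate_variants(data.frame(
    variant_id = tab$variant_id,
    chromosome = tab$chr,
    position = tab$pos,
    effect_allele = tab$effect_allele,
    other_allele = tab$other_allele,
    effect_size = as.numeric(tab$OR),
    stringsAsFactors = FALSE))
}

#' Write a variant weight table
#' @param weights validated weight table (see [read_weight_table()])
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
write_weight_table <- function(weights, path) {
  weights <- validate_variants(weights)
  out <- data.frame(variant_id = weights$variant_id,
                    chr = weights$chromosome,
                    pos = weights$position,
                    effect_allele = weights$effect_allele,
                    other_allele = weights$other_allele,
                    OR = weights$effect_size)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from PLINK text files (PED/MAP)
#'
#' Parses whitespace-delimited PED/MAP files and converts each genotype to an
#' effect-allele dosage using the supplied weight table. MAP variants are
#' joined to weights by chromosome + position (variant-id mismatches warn,
#' since rsID drift is common). The PLINK missing-allele code `"0"` becomes a
#' missing dosage.
#'
#' @param ped_path path to the PED file (6 leading columns, then two allele
#'   columns per variant)
#' @param map_path path to the MAP file (chromosome, id, genetic distance,
#'   position)
#' @param weights weight table from [read_weight_table()]
#' @return a [genotype_matrix()]
#' @export
read_plink_text <- function(ped_path, map_path, weights) {
  if (!file.exists(ped_path)) stopf("PED file not found: %s", ped_path)
  if (!file.exists(map_path)) stopf("MAP file not found: %s", map_path)
  weights <- validate_variants(weights)

  map <- utils::read.table(map_path, stringsAsFactors = FALSE,
                           col.names = c("chromosome", "variant_id",
                                         "cm", "position"))
  m <- nrow(map)
  key_map <- paste(map$chromosome, map$position)
  key_w <- paste(weights$chromosome, weights$position)
  idx <- match(key_map, key_w)
  if (anyNA(idx))
    stopf("MAP variant(s) absent from weight table: %s",
          paste(map$variant_id[is.na(idx)], collapse = ", "))
  drift <- map$variant_id != weights$variant_id[idx]
  if (any(drift))
    warnf("variant id mismatch between MAP and weight table for %d site(s) (joined by position): %s",
          sum(drift), paste(utils::head(map$variant_id[drift], 5), collapse = ", "))
  w <- weights[idx, , drop = FALSE]

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  lens <- lengths(fields)
  if (any(lens != want))
    stopf("ragged PED row at line %d: expected %d fields, found %d",
          which(lens != want)[1], want, lens[lens != want][1])

  n <- length(fields)
  ids <- vapply(fields, `[[`, "", 2L)
  dosage <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    a1 <- toupper(vapply(fields, `[[`, "", 6L + 2L * j - 1L))
    a2 <- toupper(vapply(fields, `[[`, "", 6L + 2L * j))
    eff <- w$effect_allele[j]; oth <- w$other_allele[j]
    for (al in list(a1, a2)) {
      bad <- !(al %in% c(eff, oth, "0"))
      if (any(bad))
        stopf("allele '%s' at variant %s (sample %s) matches neither effect (%s) nor other (%s) allele",
              al[bad][1], w$variant_id[j], ids[bad][1], eff, oth)
    }
    miss <- a1 == "0" | a2 == "0"
    dosage[, j] <- (a1 == eff) + (a2 == eff)
    dosage[miss, j] <- NA_integer_
  }
  genotype_matrix(dosage, w, sample_ids = ids)
}

#' Write genotypes to PLINK text files (PED/MAP)
#'
#' Inverse of [read_plink_text()]: dosage 2 becomes a homozygous effect-allele
#' genotype, 0 homozygous other-allele, and missing entries the PLINK `"0 0"`
#' code.
#'
#' @param G a [genotype_matrix()]
#' @param ped_path,map_path output paths
#' @param phenotype optional phenotype table; if given, the PED phenotype
#'   column is 2 for fracture cases, 1 for controls, -9 otherwise
#' @return invisibly, `c(ped_path, map_path)`
#' @export
write_plink_text <- function(G, ped_path, map_path, phenotype = NULL) {
  v <- G$variants
  utils::write.table(
    data.frame(v$chromosome, v$variant_id, 0L, v$position),
    map_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  ids <- sample_ids(G)
  ph <- rep(-9L, length(ids))
  if (!is.null(phenotype)) {
    st <- phenotype$fracture[match(ids, phenotype$sample_id)]
    ph[st %in% "case"] <- 2L
    ph[st %in% "control"] <- 1L
  }
  m <- ncol(G$dosage)
  cols <- vector("list", 2L * m)
  for (j in seq_len(m)) {
    d <- G$dosage[, j]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, v$effect_allele[j], v$other_allele[j]))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2L, v$effect_allele[j], v$other_allele[j]))
    cols[[2L * j - 1L]] <- a1
    cols[[2L * j]] <- a2
  }
  ped <- do.call(cbind, c(list(ids, ids, "0", "0", "2", as.character(ph)), cols))
  writeLines(apply(ped, 1L, paste, collapse = " "), ped_path)
  invisible(c(ped_path, map_path))
}

#' Read genotypes from a VCF file
#'
#' GT fields are converted to effect-allele dosages by joining VCF sites to
#' the weight table on chromosome + position + unordered allele pair. When
#' REF/ALT are the swap of the weight table's other/effect alleles the dosage
#' is flipped (`2 - d`). Multi-allelic sites and sites without a weight-table
#' partner are skipped with a warning; strand-ambiguous (A/T, C/G) sites are
#' resolved by allele match only, with a warning.
#'
#' @param vcf_path path to a VCF 4.x file with GT genotypes
#' @param weights weight table from [read_weight_table()]
#' @return a [genotype_matrix()] over the joined variants, in weight-table order
#' @export
read_vcf <- function(vcf_path, weights) {
  if (!file.exists(vcf_path)) stopf("VCF file not found: %s", vcf_path)
  weights <- validate_variants(weights)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt_raw <- vcf@gt
  if (colnames(gt_raw)[1] == "FORMAT") {
    fmt <- strsplit(gt_raw[, 1], ":")
    gt <- gt_raw[, -1, drop = FALSE]
    for (i in seq_len(nrow(gt))) {
      pos <- match("GT", fmt[[i]])
      if (is.na(pos)) { gt[i, ] <- NA_character_; next }
      if (pos > 1 || length(fmt[[i]]) > 1)
        gt[i, ] <- vapply(strsplit(gt[i, ], ":"), `[`, "", pos)
    }
  } else {
    gt <- gt_raw
  }

  multi <- grepl(",", fix$ALT)
  if (any(multi))
    warnf("skipping %d multi-allelic site(s)", sum(multi))

  key_w <- paste(weights$chromosome, weights$position)
  key_v <- paste(fix$CHROM, fix$POS)
  rows <- integer(0); flip <- logical(0); widx <- integer(0)
  for (i in which(!multi)) {
    j <- match(key_v[i], key_w)
    if (is.na(j)) next
    ref <- toupper(fix$REF[i]); alt <- toupper(fix$ALT[i])
    eff <- weights$effect_allele[j]; oth <- weights$other_allele[j]
    if (ref == oth && alt == eff) {
      fl <- FALSE
    } else if (ref == eff && alt == oth) {
      fl <- TRUE
    } else {
      warnf("site %s:%s alleles %s/%s do not match weight table (%s/%s); skipped",
            fix$CHROM[i], fix$POS[i], ref, alt, eff, oth)
      next
    }
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    if (comp[[eff]] == oth)
      warnf("strand-ambiguous alleles (%s/%s) at %s:%s resolved by allele match only",
            eff, oth, fix$CHROM[i], fix$POS[i])
    id <- fix$ID[i]
    if (!is.na(id) && id != "." && id != weights$variant_id[j])
      warnf("variant id mismatch at %s:%s (VCF %s, weights %s); joined by position",
            fix$CHROM[i], fix$POS[i], id, weights$variant_id[j])
    rows <- c(rows, i); flip <- c(flip, fl); widx <- c(widx, j)
  }
  if (!length(rows))
    stopf("no VCF sites overlap the weight table")

  samples <- colnames(gt)
  dosage <- matrix(NA_integer_, length(samples), length(rows))
  for (k in seq_along(rows)) {
    g <- gt[rows[k], ]
    alt_count <- vapply(strsplit(g, "[/|]"), function(al) {
      if (any(is.na(al)) || any(al == ".")) return(NA_integer_)
      sum(al == "1")
    }, integer(1))
    dosage[, k] <- if (flip[k]) 2L - alt_count else alt_count
  }
  ord <- order(widx)
  genotype_matrix(dosage[, ord, drop = FALSE],
                  weights[widx[ord], , drop = FALSE],
                  sample_ids = samples)
}

#' Write genotypes to a minimal VCF file
#'
#' Emits a sites+GT VCF 4.2 with REF = other allele and ALT = effect allele,
#' so the ALT dosage equals the stored effect-allele dosage.
#'
#' @param G a [genotype_matrix()]
#' @param path output path
#' @param swap_alleles if `TRUE`, write REF = effect allele and ALT = other
#'   allele instead (useful for exercising allele-swap handling downstream)
#' @return invisibly, `path`
#' @export
write_vcf <- function(G, path, swap_alleles = FALSE) {
  v <- G$variants
  ids <- sample_ids(G)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=osteopgs",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "FORMAT", ids), collapse = "\t"))
  gt_str <- function(d) ifelse(is.na(d), "./.",
                               c("0/0", "0/1", "1/1")[d + 1L])
  body <- vapply(seq_len(ncol(G$dosage)), function(j) {
    d <- G$dosage[, j]
    if (swap_alleles) {
      ref <- v$effect_allele[j]; alt <- v$other_allele[j]
      d <- ifelse(is.na(d), NA_integer_, 2L - d)
    } else {
      ref <- v$other_allele[j]; alt <- v$effect_allele[j]
    }
    paste(c(v$chromosome[j], v$position[j], v$variant_id[j], ref, alt,
            ".", "PASS", "GT", gt_str(d)), collapse = "\t")
  }, character(1))
  ord <- order(v$chromosome, v$position)
  writeLines(c(hdr, body[ord]), path)
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV with columns `sample_id`, `fracture` (case/control/unknown), `t_score`
#' (BMD T-criterion units, may be empty), `bmd_class`, and optional
#' `ethnicity`, `age_years`, `bmi`. When both `t_score` and `bmd_class` are
#' present their consistency with the WHO T-criterion thresholds is checked.
#'
#' @param path path to a TSV file
#' @return validated phenotype data frame
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stopf("phenotype table not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_phenotypes(tab)
}

#' Write a phenotype table
#' @param phenotype validated phenotype data frame
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
write_phenotype_table <- function(phenotype, path) {
  utils::write.table(phenotype, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write an evaluation report to disk
#'
#' Emits a JSON file at `path` carrying every report field (including the
#' decile table, ROC coordinates, and per-group score vectors, so density,
#' decile, and ROC figures can be redrawn downstream) plus tabular TSV
#' sidecars `<path minus .json>.decile.tsv` and `.roc.tsv`.
#'
#' @param report an `eval_report` from [evaluate_contrast()]
#' @param path output path for the JSON form
#' @return invisibly, `path`
#' @export
write_eval_report <- function(report, path) {
  if (!inherits(report, "eval_report")) stopf("not an eval_report")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  stem <- sub("\\.json$", "", path)
  utils::write.table(report$decile_table, paste0(stem, ".decile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$roc, paste0(stem, ".roc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an evaluation report written by [write_eval_report()]
#' @param path path to the JSON report
#' @return an `eval_report`
#' @export
read_eval_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$decile_table <- as.data.frame(x$decile_table)
  x$roc <- as.data.frame(x$roc)
  structure(x, class = "eval_report")
}
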