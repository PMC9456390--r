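#' Classify a BMD T-score by the WHO T-criterion
#'
#' T-scores above -1.0 are normal; from -2.5 to -1.0 (inclusive at both
#' boundaries) osteopenia; below -2.5 osteoporosis. The boundary values -1.0
#' and -2.5 therefore both fall in the osteopenia band.
#'
#' @param t_score numeric vector of BMD T-scores (SD units vs young-adult
#'   reference); `NA` allowed
#' @return character vector in \{"normal", "osteopenia", "osteoporosis",
#'   "unknown"\}
#' @export
classify_t_score <- function(t_score) {
  out <- rep("unknown", length(t_score))
  ok <- !is.na(t_score)
  out[ok & t_score > -1.0] <- "normal"
  out[ok & t_score <= -1.0 & t_score >= -2.5] <- "osteopenia"
  out[ok & t_score < -2.5] <- "osteoporosis"
  out
}

validate_phenotypes <- function(tab) {
  if (!"sample_id" %in% names(tab)) stopf("phenotype table needs sample_id")
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id)) stopf("duplicate sample ids in phenotype table")
  if (!"fracture" %in% names(tab)) tab$fracture <- "unknown"
  tab$fracture[is.na(tab$fracture) | tab$fracture == ""] <- "unknown"
  bad <- !tab$fracture %in% c("case", "control", "unknown")
  if (any(bad)) stopf("invalid fracture status: %s", tab$fracture[bad][1])
  if (!"t_score" %in% names(tab)) tab$t_score <- NA_real_
  tab$t_score <- as.numeric(tab$t_score)
  if (!"bmd_class" %in% names(tab)) tab$bmd_class <- classify_t_score(tab$t_score)
  tab$bmd_class[is.na(tab$bmd_class) | tab$bmd_class == ""] <- "unknown"
  bad <- !tab$bmd_class %in% c("normal", "osteopenia", "osteoporosis", "unknown")
  if (any(bad)) stopf("invalid bmd_class: %s", tab$bmd_class[bad][1])
  both <- !is.na(tab$t_score) & tab$bmd_class != "unknown"
  if (any(both)) {
    expect <- classify_t_score(tab$t_score[both])
    if (any(expect != tab$bmd_class[both]))
      stopf("bmd_class inconsistent with t_score for sample %s",
            tab$sample_id[both][expect != tab$bmd_class[both]][1])
  }
  for (col in c("ethnicity", "age_years", "bmi"))
    if (!col %in% names(tab)) tab[[col]] <- NA
  tab[, c("sample_id", "fracture", "t_score", "bmd_class",
          "ethnicity", "age_years", "bmi")]
}

#' Define a case-control contrast over a phenotype table
#'
#' Three contrasts are supported, mirroring the three prognostic models:
#' `fracture` (fracture cases vs fracture-free controls), `low_bmd`
#' (osteopenia/osteoporosis vs normal BMD), and `comorbid` (fracture cases
#' with low BMD vs fracture-free controls with normal BMD). Samples matching
#' neither rule are excluded from the contrast.
#'
#' @param phenotype validated phenotype table
#' @param name one of `"fracture"`, `"low_bmd"`, `"comorbid"`
#' @return list with `name`, `case_ids`, `control_ids`
#' @export
make_contrast <- function(phenotype, name = c("fracture", "low_bmd", "comorbid")) {
  name <- match.arg(name)
  ph <- validate_phenotypes(phenotype)
  low <- ph$bmd_class %in% c("osteopenia", "osteoporosis")
  norm <- ph$bmd_class == "normal"
  frac <- ph$fracture == "case"
  nofrac <- ph$fracture == "control"
  sel <- switch(name,
    fracture = list(case = frac, control = nofrac),
    low_bmd = list(case = low, control = norm),
    comorbid = list(case = frac & low, control = nofrac & norm))
  case_ids <- ph$sample_id[sel$case]
  control_ids <- ph$sample_id[sel$control]
  if (length(intersect(case_ids, control_ids)))
    stopf("contrast %s has overlapping case and control sets", name)
  if (!length(case_ids) || !length(control_ids))
    stopf("contrast %s has an empty case or control group", name)
  list(name = name, case_ids = case_ids, control_ids = control_ids)
}
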