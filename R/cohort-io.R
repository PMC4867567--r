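# Cohort table schema, validation and delimited-text I/O.
#
# One row per affected male. Missing values are encoded "NC" (not collected)
# on disk, case-insensitively.

COHORT_COLUMNS <- c(
  "subject_id", "family_id", "hgvs_c", "hgvs_c_2", "protein_change",
  "protein_change_2", "age", "onset_nyctalopia", "onset_other",
  "va_od", "va_os", "vf_od", "vf_os", "vf_isopter", "vf_instrument"
)

COHORT_MANDATORY <- c("subject_id", "family_id", "hgvs_c", "age")

NC_TOKEN <- "NC"

#' Coerce and validate a cohort table
#'
#' Checks the cohort schema (mandatory columns `subject_id`, `family_id`,
#' `hgvs_c`, `age`), fills optional columns with `NA`, coerces types, and
#' computes the derived per-eye logMAR columns `va_od_logmar`,
#' `va_os_logmar` from the raw acuity strings. Enforces that recorded onsets
#' do not exceed the age at assessment.
#'
#' @param x A data frame in the cohort schema.
#' @return A validated cohort tibble (class `chm_cohort`).
#' @export
as_cohort <- function(x) {
  if (inherits(x, "chm_cohort")) {
    return(x)
  }
  x <- as_tibble(x)
  missing_cols <- setdiff(COHORT_MANDATORY, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "cohort table is missing mandatory column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in setdiff(COHORT_COLUMNS, names(x))) x[[col]] <- NA
  blank_nc <- function(v) {
    v <- as.character(v)
    v[!is.na(v) & toupper(trimws(v)) %in% c(NC_TOKEN, "")] <- NA_character_
    v
  }
  chr_cols <- c(
    "subject_id", "family_id", "hgvs_c", "hgvs_c_2", "protein_change",
    "protein_change_2", "va_od", "va_os", "vf_isopter", "vf_instrument"
  )
  for (col in chr_cols) x[[col]] <- blank_nc(x[[col]])
  num_from <- function(v) suppressWarnings(as.numeric(blank_nc(v)))
  x$age <- as.integer(num_from(x$age))
  x$onset_nyctalopia <- as.integer(num_from(x$onset_nyctalopia))
  x$onset_other <- as.integer(num_from(x$onset_other))
  x$vf_od <- num_from(x$vf_od)
  x$vf_os <- num_from(x$vf_os)
  if (any(!is.na(x$age) & x$age < 1)) abort("age must be >= 1 year")
  for (col in c("onset_nyctalopia", "onset_other")) {
    bad <- !is.na(x[[col]]) & x[[col]] > x$age
    if (any(bad)) {
      abort(paste0(col, " exceeds age at assessment for subject(s): ",
        paste(x$subject_id[bad], collapse = ", ")
      ))
    }
  }
  for (col in c("vf_od", "vf_os")) {
    if (any(!is.na(x[[col]]) & (x[[col]] < 0 | x[[col]] > 180))) {
      abort("visual-field width must lie in [0, 180] degrees")
    }
  }
  x$va_od_logmar <- acuity_to_logmar(x$va_od)
  x$va_os_logmar <- acuity_to_logmar(x$va_os)
  x <- x[, c(COHORT_COLUMNS, "va_od_logmar", "va_os_logmar")]
  class(x) <- c("chm_cohort", class(x))
  x
}

#' Read a cohort table from delimited text
#'
#' Reads a CSV (or TSV) cohort file with a header row; missing values are
#' encoded `"NC"`. Returns a validated cohort tibble with derived logMAR
#' columns.
#'
#' @param path Path to the file.
#' @param delim Field delimiter, `","` by default.
#' @return A cohort tibble; see [as_cohort()].
#' @export
read_cohort <- function(path, delim = ",") {
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE
  )
  as_cohort(raw)
}

#' Write a cohort table to delimited text
#'
#' Writes the schema columns (derived logMAR columns are not written) with
#' `NA` encoded as `"NC"`. `write_cohort()` then `read_cohort()` reproduces
#' the cohort exactly.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  cohort <- as_cohort(cohort)
  readr::write_delim(cohort[, COHORT_COLUMNS], path,
    delim = delim, na = NC_TOKEN, progress = FALSE
  )
  invisible(path)
}
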