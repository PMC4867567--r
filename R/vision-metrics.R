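# Acuity / visual-field normalisation, better-eye selection, decade binning
# and Table-1-style stratified summaries.

# Semiquantitative acuity grades and their logMAR equivalents. CF/HM follow
# Schulze-Bonsel-style calibration; LP/NLP are assigned ceiling values.
SEMIQUANT_LOGMAR <- c(CF = 1.9, HM = 2.3, LP = 2.7, NLP = 3.0)

# logMAR ceiling: nothing is recorded worse than NLP.
LOGMAR_CEILING <- 3.0

#' Convert semiquantitative acuity grades to logMAR
#'
#' Counting fingers (CF), hand motion (HM), light perception (LP) and no
#' light perception (NLP) are mapped to fixed logMAR equivalents
#' (1.9, 2.3, 2.7 and 3.0 respectively).
#'
#' @param code Character vector of grades in `c("CF", "HM", "LP", "NLP")`
#'   (case-insensitive).
#' @return Numeric vector of logMAR values.
#' @examples
#' semiquant_to_logmar(c("CF", "NLP"))
#' @export
semiquant_to_logmar <- function(code) {
  code <- toupper(trimws(as.character(code)))
  bad <- !is.na(code) & !code %in% names(SEMIQUANT_LOGMAR)
  if (any(bad)) {
    abort(paste0(
      "unknown semiquantitative acuity code(s): ",
      paste(unique(code[bad]), collapse = ", ")
    ))
  }
  unname(SEMIQUANT_LOGMAR[code])
}

#' Convert a Snellen fraction to logMAR
#'
#' @param numerator,denominator Positive numerics; e.g. 20 and 40 for 20/40.
#' @return `log10(denominator / numerator)`.
#' @examples
#' snellen_to_logmar(20, 40)
#' @export
snellen_to_logmar <- function(numerator, denominator) {
  if (any(!is.finite(numerator) | numerator <= 0) ||
      any(!is.finite(denominator) | denominator <= 0)) {
    abort("Snellen numerator and denominator must be positive")
  }
  log10(denominator / numerator)
}

#' Parse recorded acuities into logMAR
#'
#' Accepts, element-wise: a numeric logMAR value (as number or string), a
#' Snellen fraction `"20/40"`, or a semiquantitative grade `"CF"`, `"HM"`,
#' `"LP"`, `"NLP"`. Values are capped at the NLP ceiling of 3.0. Unparseable
#' entries become `NA` with a warning.
#'
#' @param x Character (or numeric) vector of recorded acuities.
#' @return Numeric logMAR vector.
#' @export
acuity_to_logmar <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NC", "nc", "Nc")] <- NA_character_
  out <- rep(NA_real_, length(x))
  up <- toupper(x)
  is_code <- !is.na(up) & up %in% names(SEMIQUANT_LOGMAR)
  out[is_code] <- unname(SEMIQUANT_LOGMAR[up[is_code]])
  is_snellen <- !is.na(x) & !is_code & grepl("^\\s*\\d+\\.?\\d*\\s*/\\s*\\d+\\.?\\d*\\s*$", x)
  if (any(is_snellen)) {
    parts <- stringr::str_split_fixed(x[is_snellen], "/", 2)
    out[is_snellen] <- snellen_to_logmar(
      as.numeric(parts[, 1]), as.numeric(parts[, 2])
    )
  }
  left <- !is.na(x) & !is_code & !is_snellen
  num <- suppressWarnings(as.numeric(x[left]))
  out[left] <- num
  if (anyNA(num)) {
    warn(paste0(
      "unparseable acuity value(s) set to NA: ",
      paste(unique(x[left][is.na(num)]), collapse = ", ")
    ))
  }
  pmin(out, LOGMAR_CEILING)
}

#' Better-eye selection
#'
#' Applies the better-eye rule used throughout the analysis: the lower
#' logMAR (better acuity) or the wider visual field. A single measured eye
#' passes through; two missing eyes give `NA`.
#'
#' @param od,os Numeric vectors for right and left eye.
#' @param metric `"logmar"` (take the minimum) or `"field_width"` (maximum).
#' @return Numeric vector of better-eye values.
#' @examples
#' better_eye(0.9, 2.3, "logmar")
#' better_eye(20, 10, "field_width")
#' @export
better_eye <- function(od, os, metric = c("logmar", "field_width")) {
  metric <- match.arg(metric)
  if (metric == "logmar") pmin(od, os, na.rm = TRUE) else pmax(od, os, na.rm = TRUE)
}

#' Decade bin of an age
#'
#' Ages are grouped into closed decade intervals 1-10, 11-20, ..., 71-80.
#' Fractional ages are floored.
#'
#' @param age Numeric vector of ages in years, between 1 and 80.
#' @return A tibble with columns `lower` and `upper` (one row per age).
#' @examples
#' decade_bin(c(9, 10, 72))
#' @export
decade_bin <- function(age) {
  age <- floor(age)
  if (any(!is.finite(age) | age < 1 | age > 80)) {
    abort("age must be between 1 and 80 years")
  }
  lower <- 10L * ((as.integer(age) - 1L) %/% 10L) + 1L
  tibble(lower = lower, upper = lower + 9L)
}

decade_label <- function(lower) paste0(lower, "-", lower + 9L)

ALL_DECADE_LOWERS <- seq(1L, 71L, by = 10L)

#' Per-subject analysis values for a metric
#'
#' Extracts one analyzable value per subject: better-eye logMAR for `"va"`,
#' better-eye field width for `"vf"` (Goldmann fields recorded with an
#' isopter other than III4e are excluded). Subjects without the metric are
#' dropped.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @param metric `"va"` or `"vf"`.
#' @return Tibble with `subject_id`, `family_id`, `age`, `value`.
#' @export
cohort_metric <- function(cohort, metric = c("va", "vf")) {
  metric <- match.arg(metric)
  cohort <- as_cohort(cohort)
  if (metric == "va") {
    value <- better_eye(cohort$va_od_logmar, cohort$va_os_logmar, "logmar")
  } else {
    od <- cohort$vf_od
    os <- cohort$vf_os
    excl <- !is.na(cohort$vf_instrument) & cohort$vf_instrument == "Goldmann" &
      !is.na(cohort$vf_isopter) & cohort$vf_isopter != "III4e"
    od[excl] <- NA_real_
    os[excl] <- NA_real_
    value <- better_eye(od, os, "field_width")
  }
  tibble(
    subject_id = cohort$subject_id,
    family_id = cohort$family_id,
    age = cohort$age,
    value = value
  ) |>
    dplyr::filter(!is.na(.data$value), !is.na(.data$age))
}

#' Decade-stratified summary of a visual metric
#'
#' Reproduces the layout of a demographics table: per decade of age, the
#' number of subjects with the metric, mean/SD/median of age, and
#' mean/SD/median of the metric. Empty decades are emitted with `n = 0` and
#' missing statistics.
#'
#' @inheritParams cohort_metric
#' @return Tibble with one row per decade bin.
#' @export
stratified_summary <- function(cohort, metric = c("va", "vf")) {
  metric <- match.arg(metric)
  vals <- cohort_metric(cohort, metric)
  vals <- dplyr::bind_cols(vals, decade_bin(vals$age))
  out <- vals |>
    dplyr::group_by(.data$lower, .data$upper) |>
    dplyr::summarise(
      n = dplyr::n(),
      age_mean = mean(.data$age),
      age_sd = sd(.data$age),
      age_median = median(.data$age),
      mean = mean(.data$value),
      sd = sd(.data$value),
      median = median(.data$value),
      .groups = "drop"
    )
  tibble(lower = ALL_DECADE_LOWERS, upper = ALL_DECADE_LOWERS + 9L) |>
    dplyr::left_join(out, by = c("lower", "upper")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      decade = decade_label(.data$lower)
    ) |>
    dplyr::relocate("decade")
}

#' n-weighted pooled mean of stratified summaries
#'
#' @param strata A tibble with columns `n` and a mean column.
#' @param col Name of the mean column (default `"mean"`).
#' @return The pooled mean `sum(n * mean) / sum(n)` over strata with `n > 0`.
#' @export
pooled_mean <- function(strata, col = "mean") {
  n <- strata$n
  m <- strata[[col]]
  keep <- !is.na(m) & n > 0
  if (sum(n[keep]) == 0) abort("pooled_mean: total n is zero")
  sum(n[keep] * m[keep]) / sum(n[keep])
}

# Severity band boundaries on better-eye logMAR, closed on the better side:
# <=0.3 | (0.3, 0.54] | (0.54, 1.0] | >1.0.
SEVERITY_BREAKS <- c(-Inf, 0.3, 0.54, 1.0, Inf)
SEVERITY_LABELS <- c("<=0.3", ">0.3 to <=0.54", ">0.54 to <=1.0", ">1.0")

#' Visual-acuity severity bands per decade
#'
#' Counts subjects per decade falling into four better-eye logMAR bands
#' (boundaries 0.3, 0.54 and 1.0 logMAR, corresponding to Snellen 20/40,
#' 20/70 and 20/200).
#'
#' @inheritParams cohort_metric
#' @return Tibble with one row per decade x band: `decade`, `band`, `n`,
#'   `n_decade`, `fraction`. All decade/band combinations are present.
#' @export
severity_bands <- function(cohort) {
  vals <- cohort_metric(cohort, "va")
  grid <- tidyr::expand_grid(
    lower = ALL_DECADE_LOWERS,
    band = factor(SEVERITY_LABELS, levels = SEVERITY_LABELS)
  )
  if (nrow(vals) == 0) {
    return(grid |>
      dplyr::mutate(
        decade = decade_label(.data$lower), n = 0L, n_decade = 0L,
        fraction = NA_real_
      ) |>
      dplyr::select("decade", "band", "n", "n_decade", "fraction"))
  }
  vals <- dplyr::bind_cols(vals, decade_bin(vals$age)) |>
    dplyr::mutate(band = cut(.data$value,
      breaks = SEVERITY_BREAKS,
      labels = SEVERITY_LABELS, right = TRUE
    ))
  counts <- vals |>
    dplyr::count(.data$lower, .data$band, .drop = FALSE)
  grid |>
    dplyr::left_join(counts, by = c("lower", "band")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::group_by(.data$lower) |>
    dplyr::mutate(
      n_decade = sum(.data$n),
      fraction = ifelse(.data$n_decade > 0, .data$n / .data$n_decade, NA_real_)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(decade = decade_label(.data$lower)) |>
    dplyr::select("decade", "band", "n", "n_decade", "fraction")
}
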