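# Synthetic cohort generator. Emulates the statistical structure of the
# published cohort: decade age structure, biphasic better-eye progression
# with heteroskedastic per-decade noise, intereye correlation via a Gaussian
# copula, truncated-normal onset ages, and the family-level mutation
# spectrum.

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the published study conditions: 128 subjects with the
#' visual-acuity decade structure, a visual-acuity break at 40 years
#' (pre-break drift 0.001, post-break 0.048 logMAR/year from a 0.05 logMAR
#' baseline) with per-decade noise SDs from the demographics table; a
#' visual-field break at 20 years with the line anchored at 38 degrees and
#' declining 0.868 degrees/year, per-decade SDs likewise; intereye Spearman
#' correlations 0.76 (acuity) and 0.95 (fields); onset of nyctalopia
#' N(12.6, 8.4) and of other symptoms N(19.7, 11.0), truncated at one year
#' and censored at the assessment age; family mutation classes drawn with
#' the published family-count weights; fields measured in half the subjects.
#'
#' @param n_subjects Number of subjects.
#' @param age_decade_counts Integer counts per decade 1-10 ... 71-80. If they
#'   sum to `n_subjects` they are used exactly, otherwise as sampling
#'   weights.
#' @param va_break_age,va_baseline,va_slope_pre,va_slope_post Visual-acuity
#'   biphasic model: break age (years), baseline logMAR, pre- and post-break
#'   slopes (logMAR/year).
#' @param va_noise_sd_by_decade Per-decade SD of the acuity noise (logMAR).
#' @param vf_break_age,vf_anchor_width,vf_slope_post Visual-field model:
#'   break age, width at the break (degrees) and post-break decline
#'   (degrees/year); above the break the mean follows
#'   `max(0, anchor - slope * (age - break))`.
#' @param vf_plateau_mean Mean field width (degrees) of the high-variance
#'   plateau below the break age, matching the published pre-break decade
#'   means.
#' @param vf_noise_sd_by_decade Per-decade SD of the field noise (degrees).
#' @param intereye_rho_va,intereye_rho_vf Target intereye Spearman
#'   correlations.
#' @param onset_nyct_mean,onset_nyct_sd,onset_other_mean,onset_other_sd
#'   Normal onset-age parameters (years), truncated at >= 1.
#' @param vf_fraction_measured Fraction of subjects with visual fields.
#' @param family_size_probs Probabilities of family sizes 1, 2, 3 (defaults
#'   give roughly 106 families per 128 subjects).
#' @param recode_semiquant If `TRUE`, generated acuities of 1.9 logMAR or
#'   worse are written as the nearest semiquantitative code (CF/HM/LP/NLP)
#'   to exercise the conversion path.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 128,
                          age_decade_counts = c(10, 28, 17, 19, 24, 15, 12, 3),
                          va_break_age = 40,
                          va_baseline = 0.05,
                          va_slope_pre = 0.001,
                          va_slope_post = 0.048,
                          va_noise_sd_by_decade =
                            c(0.118, 0.126, 0.059, 0.172, 0.497, 0.765, 0.845, 0.231),
                          vf_break_age = 20,
                          vf_anchor_width = 38,
                          vf_slope_post = 0.868,
                          vf_plateau_mean = 73.5,
                          vf_noise_sd_by_decade = c(51, 56, 45, 11, 9, 6, 2, 2),
                          intereye_rho_va = 0.76,
                          intereye_rho_vf = 0.95,
                          onset_nyct_mean = 12.6, onset_nyct_sd = 8.4,
                          onset_other_mean = 19.7, onset_other_sd = 11.0,
                          vf_fraction_measured = 0.5,
                          family_size_probs = c(0.83, 0.13, 0.04),
                          recode_semiquant = FALSE) {
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' Generator configuration for a visual-field analysis cohort
#'
#' A [cohort_config()] preset matching the visual-field arm of the study:
#' 64 subjects with the visual-field decade structure and fields measured in
#' every subject.
#'
#' @param n_subjects Number of subjects (default 64).
#' @param ... Further overrides passed to [cohort_config()].
#' @export
vf_cohort_config <- function(n_subjects = 64, ...) {
  cohort_config(
    n_subjects = n_subjects,
    age_decade_counts = c(5, 16, 7, 7, 15, 10, 4, 0),
    vf_fraction_measured = 1,
    ...
  )
}

validate_config <- function(cfg) {
  stopifnot_cfg <- function(ok, msg) if (!ok) abort(paste0("invalid config: ", msg))
  stopifnot_cfg(cfg$n_subjects >= 1, "n_subjects must be >= 1")
  stopifnot_cfg(
    length(cfg$age_decade_counts) == 8 && all(cfg$age_decade_counts >= 0) &&
      sum(cfg$age_decade_counts) > 0,
    "age_decade_counts must be 8 non-negative counts"
  )
  stopifnot_cfg(
    all(cfg$va_noise_sd_by_decade > 0) && all(cfg$vf_noise_sd_by_decade > 0),
    "noise SDs must be positive"
  )
  stopifnot_cfg(
    abs(cfg$intereye_rho_va) <= 1 && abs(cfg$intereye_rho_vf) <= 1,
    "intereye correlations must lie in [-1, 1]"
  )
  stopifnot_cfg(
    cfg$vf_fraction_measured >= 0 && cfg$vf_fraction_measured <= 1,
    "vf_fraction_measured must lie in [0, 1]"
  )
  stopifnot_cfg(
    cfg$onset_nyct_sd > 0 && cfg$onset_other_sd > 0,
    "onset SDs must be positive"
  )
  invisible(cfg)
}

# Pearson correlation of the Gaussian copula that induces a target Spearman
# correlation for continuous marginals.
copula_pearson_rho <- function(rho_spearman) 2 * sin(pi * rho_spearman / 6)

# Constraining the fellow eye to be no better than the designated better eye
# raises the realized intereye Spearman correlation above the copula input.
# This grid maps copula input Spearman to the realized Spearman of
# (X, max(X, Y)) for a standard bivariate normal pair; it was computed once
# by Monte Carlo (2e6 pairs per point) and is inverted at run time so that
# the realized correlation matches the configured target. Targets below the
# floor of ~0.60 are not attainable under the worse-eye constraint.
COPULA_CAL_IN <- seq(0, 0.99, by = 0.03)
COPULA_CAL_OUT <- c(
  0.6008, 0.6144, 0.6277, 0.6408, 0.6553, 0.6685, 0.6814, 0.6941, 0.7081,
  0.7209, 0.7334, 0.7455, 0.7584, 0.7713, 0.7836, 0.7955, 0.8078, 0.8196,
  0.8313, 0.8433, 0.8541, 0.8658, 0.8777, 0.8888, 0.9002, 0.9112, 0.9223,
  0.9331, 0.9440, 0.9549, 0.9653, 0.9758, 0.9863, 0.9966
)

calibrate_copula_spearman <- function(target) {
  if (target <= COPULA_CAL_OUT[1]) {
    return(0)
  }
  if (target >= COPULA_CAL_OUT[length(COPULA_CAL_OUT)]) {
    return(0.99)
  }
  stats::approx(COPULA_CAL_OUT, COPULA_CAL_IN, xout = target)$y
}

# Correlated standard-normal pair.
rnorm_pair <- function(n, rho) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cbind(z1, z2)
}

rtruncnorm_min <- function(n, mean, sd, lower = 1) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower)
  }
  out
}

va_mean_line <- function(age, cfg) {
  cfg$va_baseline + cfg$va_slope_pre * pmin(age, cfg$va_break_age) +
    cfg$va_slope_post * pmax(age - cfg$va_break_age, 0)
}

vf_mean_line <- function(age, cfg) {
  ifelse(
    age <= cfg$vf_break_age,
    cfg$vf_plateau_mean,
    pmax(0, cfg$vf_anchor_width - cfg$vf_slope_post * (age - cfg$vf_break_age))
  )
}

recode_va <- function(x) {
  codes <- c(CF = 1.9, HM = 2.3, LP = 2.7, NLP = 3.0)
  ifelse(x >= 1.9,
    names(codes)[max.col(-abs(outer(x, codes, "-")), ties.method = "first")],
    format(x, trim = TRUE)
  )
}

#' Simulate a synthetic CHM cohort
#'
#' Generates a cohort table with the structure assumed by the analysis (see
#' [cohort_config()] for the generative model). The result is deterministic
#' given a seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; required for reproducibility.
#' @return A cohort tibble (see [as_cohort()]).
#' @examples
#' cohort <- simulate_cohort(cohort_config(), seed = 1)
#' nrow(cohort)
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, config)
  }
  validate_config(config)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_cohort(config, seed = NULL)))
  }
  cfg <- config
  n <- cfg$n_subjects

  # ages per decade
  counts <- cfg$age_decade_counts
  if (sum(counts) == n) {
    dec <- rep(seq_len(8), counts)
  } else {
    dec <- sample(seq_len(8), n, replace = TRUE, prob = counts / sum(counts))
  }
  lower <- 10L * (dec - 1L) + 1L
  age <- lower + sample.int(10, n, replace = TRUE) - 1L

  # families and mutation assignment from the published spectrum
  sizes <- sample(1:3, n, replace = TRUE, prob = cfg$family_size_probs)
  fam_of_subject <- rep(seq_along(sizes), sizes)[seq_len(n)]
  n_fam <- max(fam_of_subject)
  tab2 <- chm_table2()
  fam_rows <- sample.int(nrow(tab2), n_fam, replace = TRUE)
  fam_tab <- tab2[fam_rows[fam_of_subject], ]

  # The better-eye value carries the biphasic model (its marginal is the
  # mean line plus the per-decade noise); the fellow eye is drawn from the
  # same age-conditional marginal through a Gaussian copula at the target
  # Spearman correlation and is constrained to be no better, so that the
  # analysis-side better-eye rule recovers exactly the modelled values.
  sd_va <- cfg$va_noise_sd_by_decade[dec]
  z_va <- rnorm_pair(
    n, copula_pearson_rho(calibrate_copula_spearman(cfg$intereye_rho_va))
  )
  mu_va <- va_mean_line(age, cfg)
  va_better <- mu_va + sd_va * z_va[, 1]
  va_fellow <- pmax(va_better, mu_va + sd_va * z_va[, 2]) # worse = higher logMAR
  va_better <- round(pmin(pmax(va_better, -0.1), 3.0), 3)
  va_fellow <- round(pmin(pmax(va_fellow, -0.1), 3.0), 3)
  od_is_better_va <- runif(n) < 0.5
  va_od <- ifelse(od_is_better_va, va_better, va_fellow)
  va_os <- ifelse(od_is_better_va, va_fellow, va_better)

  # visual fields: better eye = wider field
  sd_vf <- cfg$vf_noise_sd_by_decade[dec]
  z_vf <- rnorm_pair(
    n, copula_pearson_rho(calibrate_copula_spearman(cfg$intereye_rho_vf))
  )
  mu_vf <- vf_mean_line(age, cfg)
  vf_better <- mu_vf + sd_vf * z_vf[, 1]
  vf_fellow <- pmin(vf_better, mu_vf + sd_vf * z_vf[, 2]) # worse = narrower
  vf_better <- round(pmin(pmax(vf_better, 0), 180), 1)
  vf_fellow <- round(pmin(pmax(vf_fellow, 0), 180), 1)
  od_is_better_vf <- runif(n) < 0.5
  vf_od <- ifelse(od_is_better_vf, vf_better, vf_fellow)
  vf_os <- ifelse(od_is_better_vf, vf_fellow, vf_better)
  has_vf <- runif(n) < cfg$vf_fraction_measured
  vf_od[!has_vf] <- NA_real_
  vf_os[!has_vf] <- NA_real_

  # onsets, censored at the assessment age
  nyct <- round(rtruncnorm_min(n, cfg$onset_nyct_mean, cfg$onset_nyct_sd))
  other <- round(rtruncnorm_min(n, cfg$onset_other_mean, cfg$onset_other_sd))
  nyct[nyct > age] <- NA_integer_
  other[other > age] <- NA_integer_

  va_od_chr <- if (cfg$recode_semiquant) recode_va(va_od) else as.character(va_od)
  va_os_chr <- if (cfg$recode_semiquant) recode_va(va_os) else as.character(va_os)

  as_cohort(tibble(
    subject_id = sprintf("SYN%03d", seq_len(n)),
    family_id = sprintf("F%03d", fam_of_subject),
    hgvs_c = fam_tab$hgvs_c,
    hgvs_c_2 = fam_tab$hgvs_c_2,
    protein_change = fam_tab$protein_change,
    protein_change_2 = fam_tab$protein_change_2,
    age = as.integer(age),
    onset_nyctalopia = as.integer(nyct),
    onset_other = as.integer(other),
    va_od = va_od_chr,
    va_os = va_os_chr,
    vf_od = vf_od,
    vf_os = vf_os,
    vf_isopter = ifelse(has_vf, "III4e", NA_character_),
    vf_instrument = ifelse(has_vf, "Goldmann", NA_character_)
  ))
}

chm_extdata <- function(file) {
  path <- system.file("extdata", file, package = "chmnat")
  if (!nzchar(path)) {
    # during in-source development
    path <- file.path("inst", "extdata", file)
  }
  path
}

#' Published-table fixtures
#'
#' Transcriptions of the published summary tables shipped with the package:
#' the decade-stratified demographics (`chm_table1()`), the family mutation
#' table (`chm_table2()`, 106 families), the missense stability table
#' (`chm_table3()`) and the missense-subject clinical table (`chm_table5()`,
#' returned as a cohort tibble).
#'
#' @return A tibble (or cohort tibble for `chm_table5()`).
#' @export
chm_table1 <- function() {
  readr::read_csv(chm_extdata("table1_strata.csv"),
    col_types = "ciiidddddd", progress = FALSE
  )
}

#' @rdname chm_table1
#' @export
chm_table2 <- function() {
  readr::read_tsv(chm_extdata("table2_mutations.tsv"),
    col_types = "iccccc", progress = FALSE, na = ""
  )
}

#' @rdname chm_table1
#' @export
chm_table3 <- function() {
  readr::read_csv(chm_extdata("table3_stability.csv"),
    col_types = "cddd", progress = FALSE
  )
}

#' @rdname chm_table1
#' @export
chm_table5 <- function() {
  read_cohort(chm_extdata("table5_missense_subjects.csv"))
}

#' @rdname chm_table1
#' @export
table_fixtures <- function() {
  list(
    table1 = chm_table1(), table2 = chm_table2(),
    table3 = chm_table3(), table5 = chm_table5()
  )
}
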