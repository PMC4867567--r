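# Mutation-spectrum goodness-of-fit comparison, two-state unfolding
# propensities from protein stability free-energy changes, and the
# time-to-detectable-change trial-design calculator.

# The ten mutation categories conventionally used for genome-wide
# mutation-spectrum comparisons (HGMD-style).
HGMD_CATEGORIES <- c(
  "missense", "nonsense", "splice", "regulatory", "small_deletion",
  "small_insertion", "small_indel", "gross_deletion",
  "gross_insertion_duplication", "complex"
)

#' Chi-square goodness-of-fit comparison of a mutation spectrum
#'
#' Pearson chi-square test of observed category counts against a reference
#' proportion vector (expected counts `N * reference`), with `k - 1` degrees
#' of freedom.
#'
#' @param observed Non-negative integer vector of category counts.
#' @param reference Positive proportions over the same categories, summing
#'   to 1.
#' @return List with `categories`, `observed`, `reference`, `chi2`, `df`,
#'   `p`.
#' @examples
#' spectrum_chisq(c(8, 2), c(0.5, 0.5))
#' @export
spectrum_chisq <- function(observed, reference) {
  if (length(observed) != length(reference)) {
    abort("spectrum_chisq: observed and reference lengths differ")
  }
  if (abs(sum(reference) - 1) > 1e-9) {
    abort("spectrum_chisq: reference proportions must sum to 1")
  }
  if (any(reference <= 0)) {
    abort("spectrum_chisq: every reference proportion must be positive")
  }
  if (sum(observed) < 1) abort("spectrum_chisq: no observations")
  test <- suppressWarnings(chisq.test(observed, p = reference))
  list(
    categories = names(observed) %||% as.character(seq_along(observed)),
    observed = unname(observed), reference = unname(reference),
    chi2 = unname(test$statistic), df = unname(test$parameter),
    p = unname(test$p.value)
  )
}

#' Two-state unfolding propensity from a stability free-energy change
#'
#' Under a two-state (folded/unfolded) Boltzmann model, a destabilisation
#' free energy `ddG` (kcal/mol, positive = destabilising) gives an unfolding
#' propensity `U = exp(ddG/rt) / (1 + exp(ddG/rt))` and folding propensity
#' `F = 1 - U`. The effective `rt` constant defaults to 0.6 kcal/mol, the
#' single value that reproduces the published propensity table to three
#' decimals; it is an inferred calibration, not a printed formula.
#'
#' @param ddg Numeric vector of stability free-energy changes (kcal/mol).
#' @param rt Positive effective RT constant in kcal/mol.
#' @return Tibble with columns `ddg`, `u`, `f`.
#' @examples
#' unfolding_propensity(0.467)
#' @export
unfolding_propensity <- function(ddg, rt = 0.6) {
  if (!is.finite(rt) || rt <= 0) abort("unfolding_propensity: rt must be > 0")
  u <- plogis(ddg / rt)
  tibble(ddg = ddg, u = u, f = 1 - u)
}

#' Stability table for a set of mutants
#'
#' @param mutants Data frame with columns `mutant` and `ddg`.
#' @inheritParams unfolding_propensity
#' @param digits Rounding applied to the propensities for reporting
#'   (default 3, matching published precision); `NULL` for no rounding.
#' @return Tibble `mutant`, `ddg`, `u`, `f`.
#' @export
stability_table <- function(mutants, rt = 0.6, digits = 3) {
  df <- as_tibble(mutants)
  prop <- unfolding_propensity(df$ddg, rt = rt)
  out <- tibble(mutant = df$mutant, ddg = df$ddg, u = prop$u, f = prop$f)
  if (!is.null(digits)) {
    out$u <- round(out$u, digits)
    out$f <- round(out$f, digits)
  }
  out
}

#' Additivity check for a double mutant
#'
#' Compares the stability change of a double mutant with the sum of its
#' single-mutant changes and reports the unfolding propensity of each.
#'
#' @param ddg_single_a,ddg_single_b,ddg_double Stability free-energy changes
#'   (kcal/mol).
#' @inheritParams unfolding_propensity
#' @param tol Absolute tolerance for calling the effect additive.
#' @return One-row tibble with the three `ddg` values and propensities, the
#'   expected additive `ddg_sum`, the `deviation` (double minus sum) and an
#'   `additivity` label (`"additive"`, `"sub-additive"`, `"super-additive"`).
#' @export
double_mutant_check <- function(ddg_single_a, ddg_single_b, ddg_double,
                                rt = 0.6, tol = 1e-8) {
  ddg_sum <- ddg_single_a + ddg_single_b
  deviation <- ddg_double - ddg_sum
  additivity <- if (abs(deviation) <= tol) {
    "additive"
  } else if (deviation < 0) "sub-additive" else "super-additive"
  tibble(
    ddg_a = ddg_single_a, ddg_b = ddg_single_b, ddg_double = ddg_double,
    ddg_sum = ddg_sum, deviation = deviation, additivity = additivity,
    u_a = unfolding_propensity(ddg_single_a, rt)$u,
    u_b = unfolding_propensity(ddg_single_b, rt)$u,
    u_double = unfolding_propensity(ddg_double, rt)$u
  )
}

#' Time to a detectable change in visual-field width
#'
#' With a measurement variability equal to a fixed fraction of the baseline
#' field width (within/intervisit Goldmann variability, 17-22 percent), the
#' time for a linear decline to exceed one variability half-width of the
#' baseline is `variability_fraction * baseline_width / rate`.
#'
#' @param baseline_width Baseline field width in degrees, > 0.
#' @param rate Decline rate in degrees/year, > 0.
#' @param variability_fraction Fraction of baseline regarded as measurement
#'   variability (default 0.22).
#' @return Years to a detectable change (unrounded).
#' @examples
#' time_to_detectable_change(38, 0.868)
#' @export
time_to_detectable_change <- function(baseline_width, rate,
                                      variability_fraction = 0.22) {
  if (any(!is.finite(rate) | rate <= 0)) {
    abort("time_to_detectable_change: rate must be > 0 (no detectable change)")
  }
  if (any(!is.finite(baseline_width) | baseline_width <= 0)) {
    abort("time_to_detectable_change: baseline width must be > 0")
  }
  variability_fraction * baseline_width / rate
}

#' Predicted baseline visual-field width at a given age
#'
#' Linear extrapolation of the post-break field decline from an anchor point
#' (38 degrees at age 20 by default), floored at zero.
#'
#' @param age Age in years, at or above `anchor_age`.
#' @param anchor_age,anchor_width Anchor of the fitted line.
#' @param rate Decline rate in degrees/year.
#' @return Predicted width in degrees.
#' @examples
#' predicted_baseline(40)
#' @export
predicted_baseline <- function(age, anchor_age = 20, anchor_width = 38,
                               rate = 0.868) {
  if (any(age < anchor_age)) {
    abort("predicted_baseline: age must be at or above the anchor age")
  }
  pmax(0, anchor_width - rate * (age - anchor_age))
}

#' Trial-design estimate: years to a detectable visual-field change
#'
#' Combines [predicted_baseline()] and [time_to_detectable_change()] for a
#' subject of a given age.
#'
#' @inheritParams predicted_baseline
#' @inheritParams time_to_detectable_change
#' @return Tibble with `age`, `baseline_width`, `rate`,
#'   `variability_fraction`, `years_to_detectable`.
#' @examples
#' trial_design_estimate(c(20, 40))
#' @export
trial_design_estimate <- function(age, rate = 0.868, variability_fraction = 0.22,
                                  anchor_age = 20, anchor_width = 38) {
  baseline <- predicted_baseline(age, anchor_age, anchor_width, rate)
  tibble(
    age = age, baseline_width = baseline, rate = rate,
    variability_fraction = variability_fraction,
    years_to_detectable = time_to_detectable_change(
      baseline, rate, variability_fraction
    )
  )
}
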