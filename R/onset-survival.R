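# Kaplan-Meier onset-of-symptom analysis by genotype group, and intereye
# rank correlation. The product-limit estimator and the k-group test are
# delegated to the survival package; median extraction implements both the
# step and midpoint conventions.

#' Kaplan-Meier curve of symptom onset
#'
#' Product-limit estimator. Subjects whose symptom was never observed are
#' right-censored at their age at last assessment (`observed = FALSE`).
#'
#' @param event_ages Numeric vector of onset (or censoring) ages, >= 0.
#' @param observed Logical vector; `TRUE` for an observed onset. Defaults to
#'   all observed.
#' @param median_method `"step"` (default): the median is the first time at
#'   which survival drops to 0.5 or below. `"midpoint"`: when the curve sits
#'   exactly at 0.5, the median is interpolated halfway to the next event
#'   time.
#' @return Object of class `km_curve`: a list with `steps` (tibble of
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`), `median`
#'   (`NA` if survival never reaches 0.5) and `n`.
#' @examples
#' km_curve(c(10, 10, 11, 12, 15, 20, 30))
#' @export
km_curve <- function(event_ages, observed = NULL,
                     median_method = c("step", "midpoint")) {
  median_method <- match.arg(median_method)
  if (length(event_ages) == 0) abort("km_curve: no observations")
  if (any(!is.finite(event_ages) | event_ages < 0)) {
    abort("km_curve: event ages must be non-negative")
  }
  observed <- observed %||% rep(TRUE, length(event_ages))
  fit <- survival::survfit(
    survival::Surv(event_ages, observed) ~ 1, conf.type = "none"
  )
  steps <- tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv
  )
  med <- km_median(steps, median_method)
  structure(
    list(steps = steps, median = med, n = length(event_ages),
         median_method = median_method),
    class = "km_curve"
  )
}

km_median <- function(steps, method) {
  ev <- steps[steps$n_event > 0, ]
  at_or_below <- which(ev$survival <= 0.5 + 1e-12)
  if (length(at_or_below) == 0) {
    return(NA_real_)
  }
  i <- at_or_below[1]
  t0 <- ev$time[i]
  if (method == "midpoint" && abs(ev$survival[i] - 0.5) < 1e-12 &&
    i < nrow(ev)) {
    return((t0 + ev$time[i + 1]) / 2)
  }
  t0
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve A `km_curve`.
#' @param times Numeric vector.
#' @return Survival probabilities S(t) (right-continuous step function,
#'   S(t) = 1 before the first event).
#' @export
km_survival_at <- function(curve, times) {
  ev <- curve$steps[curve$steps$n_event > 0, ]
  vapply(times, function(t) {
    past <- ev$survival[ev$time <= t]
    if (length(past) == 0) 1 else past[length(past)]
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier onset curve: n =", x$n, "\n")
  cat("  median onset:", if (is.na(x$median)) "not reached" else x$median, "\n")
  invisible(x)
}

#' @rdname km_curve
#' @param x,object A `km_curve`.
#' @param ... Unused.
#' @export
tidy.km_curve <- function(x, ...) x$steps

#' @rdname km_curve
#' @export
glance.km_curve <- function(x, ...) {
  tibble(n = x$n, events = sum(x$steps$n_event), median = x$median)
}

#' @rdname km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(time = 0, survival = 1),
    object$steps[, c("time", "survival")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Age (years)", y = "Fraction asymptomatic") +
    ggplot2::theme_minimal()
}

#' Compare onset distributions between groups
#'
#' k-group comparison of onset survival curves by the log-rank (Mantel-Cox)
#' test, or the Peto-Wilcoxon variant.
#'
#' @param data Data frame with one row per subject.
#' @param time,status,group Column names (strings) for onset/censoring age,
#'   event indicator (logical or 0/1) and group label.
#' @param test `"logrank"` (default) or `"wilcoxon"`.
#' @return A list with `statistic` (chi-square), `df`, `p` and `groups`
#'   (tibble of labels with n and observed events).
#' @export
compare_onset <- function(data, time = "time", status = "status",
                          group = "group", test = c("logrank", "wilcoxon")) {
  test <- match.arg(test)
  df <- as_tibble(data)
  tt <- df[[time]]
  ev <- as.logical(df[[status]])
  gr <- factor(df[[group]])
  gr <- droplevels(gr)
  if (nlevels(gr) < 2) abort("compare_onset: need at least two groups")
  rho <- if (test == "logrank") 0 else 1
  sd_fit <- survival::survdiff(survival::Surv(tt, ev) ~ gr, rho = rho)
  k <- nlevels(gr)
  stat <- unname(sd_fit$chisq)
  groups <- tibble(
    group = levels(gr),
    n = as.integer(table(gr)),
    events = as.integer(tapply(ev, gr, sum))
  )
  list(
    statistic = stat, df = k - 1L,
    p = pchisq(stat, k - 1L, lower.tail = FALSE),
    groups = groups, test = test
  )
}

#' Onset ages and censoring status from a cohort
#'
#' Subjects with a recorded onset contribute an observed event at that age;
#' subjects without one are censored at their age at last assessment.
#'
#' @inheritParams cohort_metric
#' @param symptom `"nyctalopia"` or `"other"`.
#' @return Tibble with `subject_id`, `genotype_group`, `time`, `status`.
#' @export
onset_events <- function(cohort, symptom = c("nyctalopia", "other")) {
  symptom <- match.arg(symptom)
  cohort <- assign_genotype_group(as_cohort(cohort))
  onset <- if (symptom == "nyctalopia") cohort$onset_nyctalopia else cohort$onset_other
  tibble(
    subject_id = cohort$subject_id,
    genotype_group = cohort$genotype_group,
    time = ifelse(is.na(onset), cohort$age, onset),
    status = !is.na(onset)
  )
}

#' Onset analysis by genotype group
#'
#' Builds onset event data from a cohort, fits a Kaplan-Meier curve per
#' genotype group and tests for a group difference.
#'
#' @inheritParams onset_events
#' @inheritParams compare_onset
#' @inheritParams km_curve
#' @return List with `curves` (named list of [km_curve()] objects per
#'   genotype group), `comparison` (see [compare_onset()]) and `summary`
#'   (per-group onset mean/SEM among observed onsets).
#' @export
onset_analysis <- function(cohort, symptom = c("nyctalopia", "other"),
                           test = c("logrank", "wilcoxon"),
                           median_method = c("step", "midpoint")) {
  events <- onset_events(cohort, symptom)
  curves <- lapply(split(events, events$genotype_group), function(g) {
    if (nrow(g) == 0) {
      return(NULL)
    }
    km_curve(g$time, g$status, median_method = median_method)
  })
  curves <- curves[!vapply(curves, is.null, logical(1))]
  keep <- events$genotype_group %in% names(which(table(events$genotype_group) > 0))
  comparison <- compare_onset(events[keep, ],
    time = "time", status = "status",
    group = "genotype_group", test = test
  )
  summ <- events |>
    dplyr::filter(.data$status) |>
    dplyr::group_by(.data$genotype_group) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$time),
      sem = sd(.data$time) / sqrt(dplyr::n()), .groups = "drop"
    )
  list(curves = curves, comparison = comparison, summary = summ)
}

#' Mean, SEM and n of observed onset ages
#'
#' @param ages Numeric vector of onset ages (non-missing).
#' @return One-row tibble with `mean`, `sem` (`NA` for a single value), `n`.
#' @examples
#' onset_summary(c(10, 10, 20))
#' @export
onset_summary <- function(ages) {
  ages <- ages[!is.na(ages)]
  if (length(ages) == 0) abort("onset_summary: no observed onsets")
  n <- length(ages)
  tibble(
    mean = mean(ages),
    sem = if (n > 1) sd(ages) / sqrt(n) else NA_real_,
    n = n
  )
}

#' Intereye Spearman correlation
#'
#' Spearman rank correlation (midranks) between right- and left-eye values;
#' incomplete pairs are dropped.
#'
#' @param od,os Numeric vectors of the same metric in the two eyes.
#' @return One-row tibble with `rho` and `n` (complete pairs).
#' @examples
#' intereye_spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
intereye_spearman <- function(od, os) {
  keep <- complete.cases(od, os)
  od <- od[keep]
  os <- os[keep]
  if (length(od) < 3) {
    abort("intereye_spearman: need at least 3 complete pairs")
  }
  tibble(rho = cor(od, os, method = "spearman"), n = length(od))
}

#' Intereye correlation of a cohort metric
#'
#' @inheritParams cohort_metric
#' @return One-row tibble with `metric`, `rho`, `n`.
#' @export
intereye_correlation <- function(cohort, metric = c("va", "vf")) {
  metric <- match.arg(metric)
  cohort <- as_cohort(cohort)
  if (metric == "va") {
    res <- intereye_spearman(cohort$va_od_logmar, cohort$va_os_logmar)
  } else {
    res <- intereye_spearman(cohort$vf_od, cohort$vf_os)
  }
  dplyr::bind_cols(tibble(metric = metric), res)
}
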