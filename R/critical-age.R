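# Critical-age detection: iterative decade pooling with Kruskal-Wallis
# omnibus tests and Dunn pairwise comparisons (Bonferroni-corrected), then
# one ordinary least-squares regression per phase.
#
# The rank statistics are computed here from first principles (midranks,
# tie-corrected H, Dunn z with the pooled tie term) because the pooling
# procedure needs the pairwise z machinery that base R does not expose;
# agreement with stats::kruskal.test is asserted in the test suite.

rank_stats <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- length(values)
  n <- unname(n)
  r <- rank(values) # midranks
  idx <- rep(seq_along(groups), n)
  mean_ranks <- tapply(r, idx, mean)
  ties <- table(values)
  tie_sum <- sum(ties^3 - ties)
  list(N = N, n = n, mean_ranks = as.numeric(mean_ranks), tie_sum = tie_sum)
}

#' Kruskal-Wallis test over k groups
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 degrees of freedom. When every observation is identical (rank
#' variance zero) H is 0 and p is 1.
#'
#' @param groups A list of two or more non-empty numeric vectors.
#' @return A list with `H`, `df`, `p`, `n` (group sizes).
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("kruskal_wallis: need at least two groups")
  }
  if (any(lengths(groups) == 0)) abort("kruskal_wallis: empty group")
  rs <- rank_stats(groups)
  N <- rs$N
  H <- 12 / (N * (N + 1)) * sum(rs$n * (rs$mean_ranks - (N + 1) / 2)^2)
  correction <- 1 - rs$tie_sum / (N^3 - N)
  if (correction <= 0) {
    H <- 0
  } else {
    H <- H / correction
  }
  df <- length(groups) - 1L
  p <- if (H == 0) 1 else pchisq(H, df, lower.tail = FALSE)
  list(H = H, df = df, p = p, n = rs$n)
}

#' Dunn pairwise comparisons after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the pooled tie correction,
#' two-sided normal p-values, and Bonferroni adjustment over all
#' `k * (k - 1) / 2` pairs.
#'
#' @inheritParams kruskal_wallis
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble with one row per pair: `group_a`, `group_b`, `z`, `p_raw`,
#'   `p_adjusted`, `significant`.
#' @export
dunn_pairwise <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("dunn_pairwise: need at least two groups")
  }
  if (any(lengths(groups) == 0)) abort("dunn_pairwise: empty group")
  labels <- names(groups) %||% as.character(seq_along(groups))
  rs <- rank_stats(groups)
  N <- rs$N
  k <- length(groups)
  var_term <- N * (N + 1) / 12 - rs$tie_sum / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- purrr::map_dfr(seq_len(m), function(j) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    se <- sqrt(var_term * (1 / rs$n[i1] + 1 / rs$n[i2]))
    z <- if (se > 0) (rs$mean_ranks[i1] - rs$mean_ranks[i2]) / se else 0
    p_raw <- 2 * pnorm(-abs(z))
    tibble(
      group_a = labels[i1], group_b = labels[i2], z = z,
      p_raw = p_raw, p_adjusted = min(1, m * p_raw)
    )
  })
  out$significant <- out$p_adjusted < alpha
  out
}

#' Single-phase linear regression of a visual metric on age
#'
#' Ordinary least squares with a 95 percent confidence interval for the
#' slope from the t distribution on n - 2 degrees of freedom. A perfectly
#' constant response is reported as slope 0 with p = 1.
#'
#' @param ages,values Numeric vectors of equal length, n >= 3.
#' @return One-row tibble: `slope`, `intercept`, `slope_ci_low`,
#'   `slope_ci_high`, `p_slope`, `n`.
#' @export
fit_phase_regression <- function(ages, values) {
  keep <- is.finite(ages) & is.finite(values)
  ages <- ages[keep]
  values <- values[keep]
  n <- length(ages)
  if (n < 3) abort("fit_phase_regression: need at least 3 observations")
  if (var(ages) == 0) abort("fit_phase_regression: zero variance in age")
  if (diff(range(values)) == 0) {
    # constant response: exactly flat, nothing to test
    return(tibble(
      slope = 0, intercept = values[1], slope_ci_low = 0, slope_ci_high = 0,
      p_slope = 1, n = n
    ))
  }
  fit <- lm(values ~ ages)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  sm <- suppressWarnings(summary(fit)) # silence the zero-residual warning
  se <- sm$coefficients[2, 2]
  if (!is.finite(se) || se == 0) {
    # degenerate: residuals are exactly zero
    p <- if (abs(slope) > 0) 0 else 1
    ci <- c(slope, slope)
  } else {
    p <- sm$coefficients[2, 4]
    tcrit <- qt(0.975, df = n - 2)
    ci <- slope + c(-1, 1) * tcrit * se
  }
  tibble(
    slope = slope, intercept = intercept,
    slope_ci_low = ci[1], slope_ci_high = ci[2],
    p_slope = p, n = n
  )
}

#' Detect the critical age of a visual metric by iterative decade pooling
#'
#' Subjects are grouped by decade of age. Starting from the youngest decade,
#' the pooled young group is compared with the next-oldest decade using the
#' Dunn pairwise test (Bonferroni-corrected over all current pairs) within a
#' Kruskal-Wallis test over all current groups. While the comparison is not
#' significant the two groups are merged and the procedure repeats; the
#' first significant comparison fixes the critical age at the upper bound of
#' the pooled young group. If no comparison is ever significant the critical
#' age is absent and a single regression describes the whole age range.
#'
#' @inheritParams cohort_metric
#' @param alpha Significance level (default 0.05).
#' @param refit Logical; if `TRUE` (default) the Kruskal-Wallis/Dunn family
#'   is recomputed over the current grouping after each pooling step, if
#'   `FALSE` the adjacent-pair comparisons from the initial all-decade Dunn
#'   table are reused.
#' @param comparison_family Bonferroni family for the pooled-vs-next Dunn
#'   comparison. `"selected"` (default) treats the single preplanned
#'   pooled-vs-next contrast of each step as the tested family (no
#'   multiplication); `"sequential"` corrects over the maximum number of
#'   pooling steps; `"all_pairs"` corrects over all pairwise comparisons of
#'   the current grouping. The underlying z is always the Dunn statistic
#'   within the Kruskal-Wallis over all current groups.
#' @return An object of class `critical_age_result` with elements
#'   `critical_age` (integer or `NA`), `metric`, `alpha`, `trace` (one row
#'   per pooling step), `phase1`, `phase2` (phase regressions, see
#'   [fit_phase_regression()]) and `data` (the per-subject values used).
#' @examples
#' cohort <- simulate_cohort(cohort_config(), seed = 1)
#' find_critical_age(cohort, "va")
#' @export
find_critical_age <- function(cohort, metric = c("va", "vf"), alpha = 0.05,
                              refit = TRUE,
                              comparison_family = c("selected", "sequential", "all_pairs")) {
  metric <- match.arg(metric)
  comparison_family <- match.arg(comparison_family)
  vals <- cohort_metric(cohort, metric)
  vals <- dplyr::bind_cols(vals, decade_bin(vals$age))
  bins <- sort(unique(vals$lower)) # empty decades are skipped
  if (length(bins) < 2) {
    abort("find_critical_age: need at least two non-empty decade bins")
  }
  groups <- lapply(bins, function(b) vals$value[vals$lower == b])
  names(groups) <- decade_label(bins)
  family_m <- function(k) {
    switch(comparison_family,
      selected = 1,
      sequential = length(bins) - 1,
      all_pairs = k * (k - 1) / 2
    )
  }

  init_dunn <- dunn_pairwise(stats::setNames(groups, decade_label(bins)),
    alpha = alpha
  )
  trace <- list()
  pooled_idx <- 1L
  critical_age <- NA_integer_
  for (step in seq_len(length(bins) - 1L)) {
    pooled <- unlist(groups[seq_len(pooled_idx)], use.names = FALSE)
    pooled_lab <- paste0(bins[1], "-", bins[pooled_idx] + 9L)
    next_lab <- decade_label(bins[pooled_idx + 1L])
    if (refit) {
      current <- c(
        list(pooled),
        groups[seq.int(pooled_idx + 1L, length(bins))]
      )
      names(current) <- c(pooled_lab, names(groups)[seq.int(pooled_idx + 1L, length(bins))])
      kw <- kruskal_wallis(current)
      dn <- dunn_pairwise(current, alpha = alpha)
      cmp <- dn[dn$group_a == pooled_lab & dn$group_b == next_lab, ]
      m <- family_m(length(current))
    } else {
      kw <- kruskal_wallis(groups)
      cmp <- init_dunn[
        init_dunn$group_a == decade_label(bins[pooled_idx]) &
          init_dunn$group_b == next_lab,
      ]
      m <- family_m(length(bins))
    }
    cmp$p_adjusted <- min(1, m * cmp$p_raw)
    cmp$significant <- cmp$p_adjusted < alpha
    trace[[step]] <- tibble(
      step = step, pooled_bins = pooled_lab, next_bin = next_lab,
      n_pooled = length(pooled),
      n_next = length(groups[[pooled_idx + 1L]]),
      H = kw$H, df = kw$df, p_omnibus = kw$p,
      z = cmp$z, p_raw = cmp$p_raw, p_adjusted = cmp$p_adjusted,
      significant = cmp$significant
    )
    if (cmp$significant) {
      critical_age <- bins[pooled_idx] + 9L
      break
    }
    pooled_idx <- pooled_idx + 1L
  }

  if (!is.na(critical_age)) {
    young <- vals[vals$age <= critical_age, ]
    old <- vals[vals$age > critical_age, ]
    phase1 <- if (nrow(young) >= 3 && var(young$age) > 0) {
      fit_phase_regression(young$age, young$value)
    }
    phase2 <- if (nrow(old) >= 3 && var(old$age) > 0) {
      fit_phase_regression(old$age, old$value)
    }
  } else {
    phase1 <- fit_phase_regression(vals$age, vals$value)
    phase2 <- NULL
  }

  structure(
    list(
      critical_age = critical_age, metric = metric, alpha = alpha,
      trace = dplyr::bind_rows(trace), phase1 = phase1, phase2 = phase2,
      data = vals[, c("subject_id", "age", "value")]
    ),
    class = "critical_age_result"
  )
}

#' Biphasic progression report for a visual metric
#'
#' Runs [find_critical_age()] and attaches the conventional reporting sign:
#' visual acuity worsening is a positive logMAR slope, visual-field decline
#' is reported as a positive loss in degrees per year.
#'
#' @inheritParams find_critical_age
#' @return A `critical_age_result`; `glance()` on it includes
#'   `phase2_rate`, the post-break rate of change in reporting convention.
#' @export
biphasic_report <- function(cohort, metric = c("va", "vf"), alpha = 0.05,
                            refit = TRUE) {
  find_critical_age(cohort, metric, alpha = alpha, refit = refit)
}

reporting_rate <- function(x, phase) {
  ph <- x[[phase]]
  if (is.null(ph)) {
    return(NA_real_)
  }
  if (x$metric == "vf") -ph$slope else ph$slope
}

#' @export
print.critical_age_result <- function(x, ...) {
  cat("Critical-age analysis (", toupper(x$metric), ")\n", sep = "")
  if (is.na(x$critical_age)) {
    cat("  no critical age detected; single-phase fit\n")
  } else {
    cat("  critical age:", x$critical_age, "years\n")
  }
  if (!is.null(x$phase1)) {
    cat(sprintf(
      "  phase 1 slope: %.4f /year (p = %.3g, n = %d)\n",
      x$phase1$slope, x$phase1$p_slope, x$phase1$n
    ))
  }
  if (!is.null(x$phase2)) {
    cat(sprintf(
      "  phase 2 slope: %.4f /year (95%% CI %.4f to %.4f, p = %.3g, n = %d)\n",
      x$phase2$slope, x$phase2$slope_ci_low, x$phase2$slope_ci_high,
      x$phase2$p_slope, x$phase2$n
    ))
  }
  invisible(x)
}

#' @rdname find_critical_age
#' @param x A `critical_age_result`.
#' @param ... Unused.
#' @export
tidy.critical_age_result <- function(x, ...) {
  phases <- list(phase1 = x$phase1, phase2 = x$phase2)
  purrr::imap_dfr(phases, function(ph, nm) {
    if (is.null(ph)) {
      return(tibble())
    }
    dplyr::bind_cols(tibble(phase = nm), ph)
  })
}

#' @rdname find_critical_age
#' @export
glance.critical_age_result <- function(x, ...) {
  tibble(
    metric = x$metric,
    critical_age = x$critical_age,
    n = nrow(x$data),
    n_steps = nrow(x$trace),
    phase1_slope = if (is.null(x$phase1)) NA_real_ else x$phase1$slope,
    phase1_p = if (is.null(x$phase1)) NA_real_ else x$phase1$p_slope,
    phase2_slope = if (is.null(x$phase2)) NA_real_ else x$phase2$slope,
    phase2_p = if (is.null(x$phase2)) NA_real_ else x$phase2$p_slope,
    phase2_rate = reporting_rate(x, "phase2")
  )
}

#' @rdname find_critical_age
#' @param object A `critical_age_result`.
#' @export
autoplot.critical_age_result <- function(object, ...) {
  df <- object$data
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "Age (years)",
      y = if (object$metric == "va") "Better-eye VA (logMAR)" else
        "Better-eye VF width (degrees)"
    ) +
    ggplot2::theme_minimal()
  seg <- function(ph, from, to) {
    if (is.null(ph)) {
      return(NULL)
    }
    tibble(
      x = from, xend = to,
      y = ph$intercept + ph$slope * from,
      yend = ph$intercept + ph$slope * to
    )
  }
  brk <- if (is.na(object$critical_age)) max(df$age) else object$critical_age
  segs <- dplyr::bind_rows(
    seg(object$phase1, min(df$age), brk),
    if (!is.na(object$critical_age)) seg(object$phase2, brk, max(df$age))
  )
  if (!is.null(segs) && nrow(segs) > 0) {
    p <- p + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend),
      colour = "forestgreen", linewidth = 1, inherit.aes = FALSE
    )
  }
  if (!is.na(object$critical_age)) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$critical_age, linetype = "dashed", colour = "grey40"
    )
  }
  p
}
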