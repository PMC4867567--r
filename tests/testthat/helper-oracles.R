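# Independent oracles and small fixture builders used across the suite.

# Independent Kruskal-Wallis H: direct summation over ranks obtained by
# sorting, tie-corrected, written without reusing the package's rank_stats.
kw_H_oracle <- function(groups) {
  values <- unlist(groups)
  N <- length(values)
  ord <- order(values)
  r <- numeric(N)
  i <- 1
  while (i <= N) {
    j <- i
    while (j < N && values[ord[j + 1]] == values[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  offsets <- cumsum(c(0, lengths(groups)))
  H <- 0
  for (g in seq_along(groups)) {
    rg <- r[(offsets[g] + 1):offsets[g + 1]]
    H <- H + length(rg) * (mean(rg) - (N + 1) / 2)^2
  }
  H <- 12 * H / (N * (N + 1))
  tt <- table(values)
  C <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (C <= 0) 0 else H / C
}

# Exact two-sided permutation p-value of the two-group mean-rank difference
# (the k = 2 Dunn / Kruskal-Wallis statistic), over all assignments.
perm_rankdiff_p <- function(x, y) {
  values <- c(x, y)
  N <- length(values)
  r <- rank(values)
  stat <- function(idx) abs(mean(r[idx]) - mean(r[-idx]))
  obs <- stat(seq_along(x))
  picks <- utils::combn(N, length(x))
  perms <- apply(picks, 2, stat)
  mean(perms >= obs - 1e-12)
}

# Exact permutation p-value of the log-rank chi-square over all label
# assignments (two groups).
perm_logrank_p <- function(time, status, n1) {
  stat <- function(idx) {
    g <- factor(ifelse(seq_along(time) %in% idx, "a", "b"))
    survival::survdiff(survival::Surv(time, status) ~ g)$chisq
  }
  obs <- stat(seq_len(n1))
  picks <- utils::combn(length(time), n1)
  perms <- apply(picks, 2, stat)
  mean(perms >= obs - 1e-12)
}

# Closed-form simple-OLS slope and intercept from the normal equations.
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# Minimal cohort builder: one row per subject from parallel vectors.
make_cohort <- function(age, va_od = NA, va_os = NA, vf_od = NA, vf_os = NA,
                        hgvs_c = "c.757C>T", protein_change = "p.Arg253*",
                        family_id = NULL, ...) {
  n <- length(age)
  as_cohort(tibble::tibble(
    subject_id = paste0("S", seq_len(n)),
    family_id = family_id %||% paste0("F", seq_len(n)),
    hgvs_c = hgvs_c,
    protein_change = protein_change,
    age = age,
    va_od = as.character(va_od), va_os = as.character(va_os),
    vf_od = vf_od, vf_os = vf_os,
    vf_isopter = ifelse(is.na(vf_od) & is.na(vf_os), NA, "III4e"),
    vf_instrument = ifelse(is.na(vf_od) & is.na(vf_os), NA, "Goldmann"),
    ...
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
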