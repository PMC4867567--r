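# chmnat

Natural-history and genotype–phenotype analysis of choroideremia (CHM)
cohorts.

Choroideremia is an X-linked retinal dystrophy caused by mutations in the
*CHM* gene (loss of Rab escort protein 1, REP-1). Affected males develop
nyctalopia, progressive constriction of visual fields (VF) and, late in the
disease, loss of central visual acuity (VA). Designing gene-therapy trials
for CHM requires knowing when each visual metric starts to decline, how fast
it declines, and whether the mutation class predicts a milder course. This
package implements that analysis for clinicians and biostatisticians working
with cross-sectional CHM cohort tables (one row per affected male: HGVS
mutation, age, onset ages, per-eye acuity and field width), and ships a
synthetic-cohort generator with the published study conditions so the whole
pipeline is testable without patient-level data.

## The methods at the core

* **Acuity normalisation.** Snellen fractions become
  logMAR = log10(denominator/numerator); semiquantitative grades map to
  fixed values CF = 1.9, HM = 2.3, LP = 2.7, NLP = 3.0. The better eye
  (min logMAR, max field width) enters all analyses.
* **Critical age.** Subjects are binned by decade of age. Starting from the
  youngest decade, the pooled young group is compared with the next-oldest
  decade by a Dunn z test (mean-rank difference with pooled tie correction)
  within a Kruskal–Wallis test over all current groups:
  z = (r̄₁ − r̄₂) / √[(N(N+1)/12 − Σ(t³−t)/(12(N−1)))(1/n₁ + 1/n₂)].
  Non-significant neighbours are merged and the procedure repeats; the first
  significant comparison fixes the *critical age* at the upper bound of the
  pooled group. One ordinary least-squares regression of the metric on age
  is then fitted per phase.
* **Onset analysis.** Kaplan–Meier curves of self-reported onset of
  nyctalopia and of other visual symptoms, by genotype group (missense,
  REP-1 absent, other), with a log-rank comparison; subjects without a
  reported onset are right-censored at their assessment age.
* **Intereye correlation.** Spearman rank correlation between the two eyes.
* **Mutation spectrum.** HGVS c. strings are classified (whole-gene/exon
  deletion, duplication, start-codon, nonsense, frameshift, splice,
  missense) and counted per family; a Pearson chi-square compares the
  spectrum against reference proportions.
* **Protein stability.** A two-state Boltzmann model converts a stability
  free-energy change ΔΔG (kcal/mol) into an unfolding propensity
  U = exp(ΔΔG/RT)/(1 + exp(ΔΔG/RT)) with RT = 0.6 kcal/mol.
* **Trial design.** With Goldmann measurement variability equal to a
  fraction v of the baseline width B and a linear decline of r degrees/year,
  a change becomes detectable after v·B/r years.

## Worked example

```r
library(chmnat)

cohort <- simulate_cohort(cohort_config(), seed = 2)  # 128 affected males
res <- biphasic_report(cohort, "va")
res
#> Critical-age analysis (VA)
#>   critical age: 40 years
#>   phase 1 slope: 0.0018 /year (p = 0.181, n = 74)
#>   phase 2 slope: 0.0589 /year (95% CI 0.0451 to 0.0727, p = 1.55e-11, n = 54)
```

The procedure pools the first four decades (no significant Dunn comparison),
flags the pooled 1–40 group against the 41–50 decade, and reports a stable
phase (slope indistinguishable from 0 logMAR/year) followed by a declining
phase of ≈0.06 logMAR/year — the biphasic pattern the generator encodes
(true post-break slope 0.048). `autoplot(res)` draws the scatter with both
fitted segments.

```r
intereye_correlation(cohort, "va")   # rho 0.86 on this draw (n = 128)
onset_summary(cohort$onset_nyctalopia)  # mean 12.8 years, SEM 0.61 (n = 108)
trial_design_estimate(c(20, 40))
#>     age baseline_width  rate variability_fraction years_to_detectable
#>      20           38   0.868                 0.22                9.63
#>      40           20.6 0.868                 0.22                5.23
```

So a 20-year-old with a predicted 38° field needs ~9.6 years of follow-up
before his field width falls by more than the 22% measurement variability;
a 40-year-old only ~5.2 years.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "chmnat.R", package = "chmnat")` with subcommands
`simulate`, `summarize`, `severity`, `critical-age`, `survival`,
`correlation`, `spectrum`, `stability` and `trial-design`.

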