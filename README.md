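# jaderpv

Pharmacovigilance screening and onset-timing analysis for spontaneous
adverse-event reports in the JADER three-table schema (Drug, Reaction and
Demographic tables linked by report identifiers).

The package was built around a concrete use case — drug-associated
Guillain-Barré syndrome (GBS), a rare autoimmune peripheral neuropathy —
but every piece (the case definition, thresholds, windows) is
configurable, so it applies to any adverse event defined by a MedDRA
preferred-term list over this schema. It is aimed at
pharmacoepidemiologists who work with spontaneous-reporting databases and
need a tested, reproducible version of the standard desk workflow rather
than a one-off script.

## What it computes

**Disproportionality screening.** For each drug, the analysis table is
collapsed to a 2×2 contingency table (reports with/without the drug ×
with/without the event) and screened with:

- the reporting odds ratio with the Haldane–Anscombe ½ correction,
  ROR = ((a+½)(d+½)) / ((b+½)(c+½)), with a Wald 95% CI on the log scale;
- a two-sided Fisher exact p-value by full hypergeometric enumeration
  (minimum-likelihood convention), computed on the raw integer cells;
- the three-part signal rule: ROR > 1, p < 0.05, and ≥ 100 reports for
  the drug;
- volcano coordinates (ln ROR vs −log₁₀ p) for plotting.

**Time to onset.** Raw date strings are cleaned by digit dialect
(12-digit → truncate to 8, 8-digit → parse, 6-digit → impute the 15th,
4-digit → missing), the earliest administration and onset dates are
selected per report, and time to onset is the day difference **plus 0.5
days** (continuity correction), restricted to the closed window
[0.5, 365.5] days.

**Weibull onset patterns.** A two-parameter Weibull F(t) = 1 −
exp(−(t/α)^β) is fitted by maximum likelihood (profile equation for the
shape, closed-form scale), with Wald or bootstrap 95% CIs, and the failure
pattern classified from the shape CI against 1: *early* (CI upper < 1,
decreasing hazard), *wear-out* (CI lower > 1), *random* otherwise. Strata
(gender, age < 20 vs ≥ 20) are compared with the tie-corrected
Kruskal–Wallis test.

**Synthetic ground truth.** A seeded generator emits three-table datasets
with known per-drug event odds, Weibull onset profiles, date-dialect
pathologies and injected duplicates, so the whole pipeline is testable
without the real database.

## Worked example

```r
library(jaderpv)

cfg <- synthetic_config(
  profiles = list(
    drug_profile("covid_vaccine_like", 2000, gbs_odds_multiplier = 15,
                 onset_scale_alpha = 13.41, onset_shape_beta = 0.71),
    drug_profile("null_drug", 500)),
  background_event_rate = 0.002, n_background_reports = 20000, seed = 2024)

tables  <- filter_suspected(deduplicate_tables(generate_tables(cfg)))
records <- flag_events(merge_tables(tables))
screen  <- screen_signals(records)
head(screen[, c("drug", "a", "b", "ror", "ror_ci_low", "ror_ci_high",
                "p_value", "is_signal")], 3)
#>                 drug  a    b    ror ror_ci_low ror_ci_high  p_value is_signal
#> 1 covid_vaccine_like 48 1952 12.549     8.2472       19.09 1.09e-27      TRUE
#> 2 background_drug_09  3  368  2.449     0.8368        7.17 1.78e-01     FALSE
#> 3          null_drug  0  500  0.247     0.0153        3.99 2.70e-01     FALSE

fit_weibull(build_onset_table(tables, "covid_vaccine_like")$t_days)
#> Weibull fit (n = 38): alpha = 15.74 (9.46-26.18) days, beta = 0.66 (0.51-0.85)
#>   failure pattern: early; empirical median 15.0 (0.5-152.5) days
```

The planted drug (15× event odds) is the only signal: 48 of its 2,000
reports carry a flagged event against a ~0.2% background, giving a
corrected ROR of 12.5 with p ≈ 10⁻²⁷, while the null drug (ROR point
estimate below 1 with a CI spanning 1) and the background drugs stay
below the rule. The onset fit recovers an early-failure pattern — the
configured shape 0.71 lies inside the fitted CI (0.51–0.85) — meaning
reporting concentrates shortly after administration and declines.

For an end-to-end run with artifacts (`signals.csv`, volcano coordinates
with the −log₁₀ 0.05 reference line, per-drug onset tables, Weibull fits
and a deterministic JSON run report), see `run_pipeline()` /
`run_config()`, or the command-line wrapper
`inst/scripts/jaderpv-cli.R` (subcommands `simulate`, `screen`, `tto`,
`fit`, `run`).

## Scope notes

Signals from spontaneous reports are hypothesis-generating only: there is
no exposure denominator, reporting is biased, and no multiplicity
adjustment is applied (the run report states the number of tests). See
the vignette in `vignettes/gbs-signal-detection.Rmd` for the model
details, numerical choices and limitations.
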