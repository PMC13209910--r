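---
title: "Disproportionality screening and onset-timing analysis of spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening and onset-timing analysis of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Guillain-Barré syndrome (GBS) is a rare autoimmune peripheral neuropathy.
Besides infections, certain drugs — vaccines, immune checkpoint inhibitors,
TNF-α inhibitors — have been suspected of triggering it. Because the event
is rare, the practical way to generate hypotheses about drug associations is
a spontaneous adverse-event reporting database. `jaderpv` implements the
complete desk workflow for such an analysis against databases laid out in
the JADER three-table schema (a Drug table, a Reaction table and a
Demographic table linked by report identifiers): build the analysis table,
flag cases by a Standardized MedDRA Query (SMQ) style term list, screen
every drug for disproportionate reporting, and characterize the timing of
onset for drugs of interest.

Spontaneous reports have no exposure denominator and carry strong reporting
biases, so everything this package computes is hypothesis-generating. None
of its outputs are causal estimates, and the package deliberately reports
the number of statistical tests performed because no multiplicity
adjustment is applied (none is conventional in this screening setting).

## Building the analysis table

`read_tables()` reads the three CSVs with every field as text — dates in
this schema come in several "dialects" and must never be parsed silently.
Cleaning then proceeds in fixed, logged stages:

1. **Deduplication** (`deduplicate_tables()`): exact duplicate rows within
   each table are reduced to their first occurrence. Published JADER
   analyses reference a proprietary record-linkage procedure whose internal
   criteria are not public; this package's documented rule is full-row
   identity, which is conservative, reproducible, and exactly the species
   of duplicate the synthetic generator injects.
2. **Involvement filter** (`filter_suspected()`): drugs are reported as
   suspected, concomitant, or interacting; only suspected rows are counted.
3. **Merge** (`merge_tables()`): one analysis record per suspected-drug row
   × reaction row pair sharing a report identifier, with demographics
   joined as optional enrichment (a report without a demographic row keeps
   gender and age missing rather than being dropped — real tables contain
   unknown and unreported genders).
4. **Age conversion** (`convert_age()`): ages arrive as decade bands and
   are mapped to midpoints (100s → 105, 90s → 95, …, 10s → 15, under 10 →
   5). The mapping is case-insensitive and extensible via an alias table so
   that differently labelled exports (e.g. Japanese decade codes) can be
   mapped in configuration.

Case flagging (`flag_events()`) matches the reported preferred term (PT)
against the case definition **exactly**, after Unicode NFC normalization,
case folding and whitespace collapse. Substring matching is deliberately
not offered: PTs are a controlled vocabulary and substring rules
over-capture (e.g. a qualified term containing a PT as a prefix is not that
PT). The shipped default is the narrow-scope GBS SMQ (code 20000131), nine
PTs, stored as a plain-text packaged file; any other term list can be
supplied one PT per line.

## The disproportionality model

For each drug the analysis table is collapsed to a 2×2 contingency table

|            | event          | no event       |
|------------|----------------|----------------|
| drug       | a              | b              |
| all others | c              | d              |

with the **report** as the default counting unit: a report counts once per
cell, drug-positive if any of its suspected drugs is the target, and
event-positive if any of its reactions is flagged. The schema's record
arithmetic is pair-level, so a `unit = "pair"` option is exposed as well;
report-level counting is the pharmacovigilance convention and the default.

The reporting odds ratio is computed with the Haldane–Anscombe ½
correction,

$$\mathrm{ROR} = \frac{(a + \tfrac12)(d + \tfrac12)}{(b + \tfrac12)(c + \tfrac12)},$$

which keeps the estimate finite for zero cells, with a Wald 95% CI on the
log scale using the corrected cells. Independence is tested with a
two-sided Fisher's exact test computed by full hypergeometric enumeration
using the minimum-likelihood convention (the sum of the probabilities of
all tables with the observed margins no more likely than the observed one,
with a 1 × 10⁻⁷ relative tolerance treating floating-point-tied tables as
included — the convention of standard statistical software). Two numerical
choices here are deliberate:

* the ½ correction applies to the ROR and its CI **only**; the exact test
  runs on the raw integer cells, since the hypergeometric likelihood is
  undefined on non-integers. This is the only mathematically coherent way
  to combine the two.
* a table with any zero margin returns p = 1 by convention (independence
  is untestable), and this is logged.

A drug is a **signal** when all three of: ROR > 1 (strict), p < 0.05
(strict), and at least 100 reports carry the drug. The report-count
threshold is inclusive (n = 100 passes): source material for this rule
prints both a strict and an inclusive form, and the inclusive reading is
used here, configurably. `volcano_coordinates()` exports the conventional
scatter of ln ROR against −log₁₀ p with the significance reference line at
−log₁₀ 0.05.

## Time to onset

Date strings are cleaned by digit-count dialect (`clean_date()`): 12-digit
strings (date + clock time) are truncated to their first eight digits,
8-digit strings parse as YYYYMMDD, 6-digit strings (year + month) are
imputed to the 15th of the month, and 4-digit strings (year only) are
missing. Anything else, including digit strings that are not real calendar
dates, is unparseable. Dates must fall in a plausibility window,
1960-01-01 to 2025-02-28; the window is stated for administration start
dates in the source methodology and is applied to onset dates as well,
as a documented assumption.

Per report, the earliest valid administration date of the target drug
(first dose) and the earliest valid onset date of a flagged event are
selected; the time to onset is their difference in whole days **plus 0.5
days** as a continuity correction, so a same-day onset contributes 0.5.
Only values in the closed interval [0.5, 365.5] days enter the analysis:
published summary tables show 0.5-day minima, which proves the lower bound
is retained, and the same closure is applied at 365.5 by symmetry. An
onset preceding the start yields a value below 0.5 and is window-filtered
(with counts logged) rather than raised as an error. No interval-censoring
likelihood is attempted for month-imputed dates; the 15th-of-month rule is
applied verbatim.

## Weibull onset-pattern analysis

Onset times are modelled as Weibull, $F(t) = 1 - e^{-(t/\alpha)^\beta}$,
with scale α (days; the 63.2nd percentile) and shape β governing the
hazard trend. The MLE is computed by the package itself: β solves the
one-dimensional profile equation

$$\frac{\sum_i t_i^\beta \ln t_i}{\sum_i t_i^\beta} - \frac1\beta
  = \overline{\ln t},$$

whose left side is strictly increasing in β, so a Newton iteration with a
bisection safeguard inside the bracket [10⁻³, 10³] converges globally
(relative tolerance 10⁻¹⁰, at most 200 iterations); α then follows in
closed form as $(\sum t_i^\beta / n)^{1/\beta}$. Times are pre-scaled by
their maximum so the iteration cannot overflow at large β. An all-equal
sample makes β diverge and is refused as degenerate, as are samples
smaller than `fit_min_n` (default 10 — published per-drug fits go down to
n = 13, and single-observation strata are printed without fits).

Because the reference analysis was run in closed-source software whose CI
construction is unstated, the default 95% CIs are Wald intervals on
(ln α, ln β) from the observed information matrix, exponentiated; a seeded
percentile bootstrap (2,000 resamples) is available as a sensitivity
option. CI quality is validated by simulation (coverage within [93%, 97%]
at n = 271), not by matching printed intervals, which would require the
raw data. Onset times on the k + 0.5 grid are treated as exact values,
consistent with the continuity-correction treatment.

The **failure pattern** is classified from the shape CI against 1: early
(upper bound < 1, hazard decreasing — event reporting concentrates shortly
after exposure), wear-out (lower bound > 1, hazard increasing), random
otherwise (CI contains 1, roughly constant hazard).

Group contrasts (gender; age under vs at least 20 years) use the
tie-corrected Kruskal–Wallis test with the χ² approximation, which for two
groups is the squared normal approximation of the Wilcoxon rank-sum test —
matching the joint "Wilcoxon/Kruskal–Wallis" labelling conventional in
this literature. No continuity correction is applied. An exact
two-group permutation mode exists for small samples.

## The synthetic-report generator

Nothing in a desk validation can come from the real database, so
`generate_tables()` produces three-table datasets with known ground truth.
Its defaults are the study conditions the package is validated under:

* background flagged-event rate 0.067% of reports — the published
  proportion of GBS records in the real analysis table;
* accrual window April 2004 to February 2025, with administration starts
  sampled at least 366 days before the window end so a year of follow-up
  fits inside it;
* date dialect mix 85% 8-digit / 5% each of the 4-, 6- and 12-digit forms;
* a Poisson(0.3) number of extra concomitant background drugs per report —
  the per-report drug-count distribution is not documented for the real
  database, so this is a free parameter chosen once as a realistic level
  of polypharmacy in spontaneous reports.

Per configured drug profile, the generator plants reports whose event odds
are a configured multiple of the background odds (so the realized 2×2 odds
ratio converges to the multiplier), and flagged events in those reports
get onset dates at start + ⌊Weibull(α, β)⌋ days — floored to whole days so
that the pipeline's +0.5-day correction reconstructs interval midpoints.
Involvement mixes plant non-suspected rows for the same drug, a decoy PT
vocabulary exercises the negative flagging path, and a configurable
fraction of rows is re-injected as exact duplicates (the only duplicate
species the dedup rule claims to remove). Gender and age are sampled
independently of event status, keeping ground truth analytically simple.
Everything is driven by one seed; identical configurations and seeds yield
byte-identical tables, and a `bookkeeping` attribute records per-report
truth (event status, floored onset day, the raw pre-floor draw, dialects,
injected duplicate counts) for oracle-style testing.

What the generator does **not** emulate: reporting-volume time trends,
follow-up report versioning, Japanese-language drug dictionaries, and any
dependence of demographics on event status. Passing tests therefore show
that the statistical machinery is correct under the stated generative
model, not that real-database biases are overcome.

## Validation problem sizes

The shipped test-suite and acceptance script exercise, among others:
Fisher's exact p against full enumeration for **all** 2×2 tables with
total ≤ 60; Weibull recovery over 1,000 replicates at n = 271 from
(α, β) = (13.41, 0.71) — a published COVID-19 vaccine onset profile —
checking shape bias below 5% and CI coverage in [93%, 97%]; odds-ratio
convergence at 50,000 planted reports; and end-to-end signal recovery of
3 planted drugs (odds multiplier 10) among 20 null drugs and ~150,000
background reports, alongside a null-only false-signal rate check at the
nominal α. These sizes were chosen to make the sampling error of each
check small relative to its tolerance.

## Known limitations

* The dedup rule removes exact duplicates only; cross-report linkage of
  the same patient (follow-up reports) is out of scope.
* Month-imputed dates shift onset intervals by up to ±15 days; with the
  default dialect mix this affects a small minority of records, and such
  records are identifiable by their provenance label.
* The signal rule is the classical frequentist triple; Bayesian
  disproportionality statistics (IC, EBGM) are not implemented.
* Printed CIs from the reference analysis cannot be matched bit-exactly
  without the raw data; CI correctness is established by coverage
  simulation instead.
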