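---
title: "Methods: Triple Whammy AKI signal and time-to-onset analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Triple Whammy AKI signal and time-to-onset analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twaki)
```

## The problem

Concurrent use of a renin-angiotensin-system inhibitor (RASI), a diuretic,
and an NSAID — the "Triple Whammy" (TW) — is a well-documented precipitant
of acute kidney injury (AKI): RASIs relax the efferent arteriole, diuretics
deplete volume, and NSAIDs constrict the afferent arteriole, so the
glomerulus loses perfusion pressure from three directions at once.
Spontaneous adverse-event report databases such as JADER (the Japanese
PMDA's reporting system) allow two complementary questions to be asked at
scale:

1. **Signal**: are AKI reports over-represented among TW-exposed reports
   relative to reports without TW drugs? (disproportionality analysis)
2. **Timing**: when AKI does occur under a TW combination, how long after
   the last combination drug was started, and does the hazard fall or rise
   with time? (time-to-onset analysis)

`twaki` implements both stages plus everything around them: report-table
ingest, cohort filtering, exposure classification, and a synthetic
report-database generator with known ground truth so the whole pipeline is
testable without access to the live database.

## Cohort construction

Reports arrive as three linked tables — DEMO (case demographics), DRUG
(one row per drug per case), REAC (one row per reaction per case) — read
through a configurable *dialect* (delimiter, encoding, header mapping), so
release-specific column names and encodings stay out of the code.

Filtering follows the standard flow for this analysis: cases with unknown
sex or age band are removed, then cases under 20 years (NSAIDs are rarely
prescribed to children in Japan). Ages exist only as decade bands, so
"elderly" means band lower bound ≥ 70. AKI status is any-match of reaction
Preferred Terms against a configurable PT list in the style of the
standardized MedDRA query for acute renal failure; the shipped list is a
plain-text default, not the licensed MedDRA export.

Exposure classification applies three field-specific rules:

* every involvement category (suspect / concomitant / interaction) counts
  as exposure;
* aspirin never counts as an NSAID (it is overwhelmingly low-dose
  antiplatelet therapy), enforced structurally: aspirin names are removed
  from the NSAID set when the `drug_lists` object is built;
* a case whose only NSAID exposure is topical is NSAID-naive. An unknown
  route counts as systemic, because only *confirmed* topical-only use is
  excluded.

Matching is exact after normalization (trim, case-fold, width-unification).
We deliberately avoid fuzzy matching: classification must be auditable, and
brand-name coverage belongs in the editable YAML lists, not in string
distance heuristics. Each case then carries one of eight combination
patterns {NONE, R, D, N, RD, RN, DN, RDN}, a pure function of the three
class flags.

## Disproportionality

For a 2×2 table (`a` AKI / `b` other reports exposed, `c` AKI / `d` other
reports in the reference stratum) the reporting odds ratio is

$$\mathrm{ROR} = \frac{a/b}{c/d}, \qquad
\mathrm{CI} = \exp\!\left(\ln \mathrm{ROR} \pm z_{1-\alpha/2}
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right),$$

with a signal declared when the CI lower bound exceeds 1. The Wald
construction on the log scale is the standard in the disproportionality
literature; `alpha` defaults to 0.05 (z = 1.959964). Zero cells are an
error by default; the Haldane–Anscombe +0.5 correction is available as an
explicit option (`zero_policy = "haldane"`) and is flagged in the result,
never applied silently.

Adjusted RORs come from a binomial logistic regression of the AKI
indicator on pattern indicators (reference: no TW drug) plus male sex,
elderly, any AKI-risk drug, and reporting year. The fit is the IRLS
maximum-likelihood fit of `stats::glm`; the package adds the diagnostics a
reviewer wants: the analytic gradient norm $\|X^\top(y-\hat\mu)\|$ at the
optimum, a separation check (coefficients diverging past ±10 abort with a
dedicated error), and a rank check on the design matrix. Reporting year is
continuous (centered) by default, categorical one-hot optionally — the
choice is a config flag because neither coding is canonical. The pooled
single/double/triple rows come from a second fit with the pattern factor
collapsed to combination counts, matching how pooled rows are usually
reported.

## Time-to-onset

Only AKI cases in a TW pattern with complete dates enter: the earliest
start date per involved class (a later re-start of the same drug does not
reset the clock — we take first administration per class), a complete AKI
onset date, and onset not before the last start. The duration is

* `day0` (default): onset − last start in days, so onset on the start day
  is 0 days;
* `day1`: the same value plus one (the start day counts as day 1).

Both conventions circulate in this literature, so the choice is a config
flag rather than a constant; reproduction work should try both. Cases
where two or more class start dates tie are *simultaneous*: they stay in
pattern-level totals but leave order-stratified rows, whose meaning
depends on a well-defined "added-to" order.

### Weibull shape test

The two-parameter Weibull MLE is computed by a one-dimensional root solve
of the profile score in the shape $k$,

$$\frac1k + \overline{\ln t} -
\frac{\sum t_i^k \ln t_i}{\sum t_i^k} = 0,$$

with the scale closed-form given $k$. The score is monotone decreasing, so
bracketing plus `uniroot` at tolerance 1e-10 is both fast and certain;
weights $t_i^k$ are evaluated in log space to avoid overflow for large
durations. The shape CI is a Wald interval on $\ln k$ from the observed
information (numeric Hessian at the optimum). Shape < 1 means early
failure (decreasing hazard), 1 random failure, > 1 wear-out failure; the
default classification is conservative, requiring the whole CI to sit
beyond 1. Zero durations (onset on the start day) are outside Weibull
support: the default maps 0 to 0.5 days; excluding zeros or shifting all
durations by one day are alternatives, because no single convention is
canonical and the choice visibly moves small-duration shape estimates.

The fitting minimum is 3 strictly positive, non-identical durations;
degenerate samples abort with a structured error rather than returning a
boundary fit.

### Cumulative incidence and medians

Every record is an observed event — a report without an onset date never
enters — so the Kaplan–Meier estimator reduces exactly to the empirical
CDF, and the package computes it that way (the test suite cross-checks
against `survival::survfit`). The median is the first event time at which
cumulative incidence reaches 50%, the convention used when reading medians
off cumulative-incidence plots.

### Gehan generalized Wilcoxon

Two onset distributions are compared with the Gehan–Breslow statistic
$W = \sum_{i,j} \operatorname{sign}(b_j - a_i)$ over all cross-pairs (ties
score 0), the natural uncensored special case of the generalized Wilcoxon
and the variant implemented here (Peto–Prentice is out of scope: one
well-defined, oracle-testable choice). The default p-value is a normal
approximation with the permutation variance of $W$ conditional on the
pooled sample and a continuity correction — the same convention base R's
`wilcox.test` uses. The correction matters at small samples: the exact
permutation distribution carries a discrete atom at $|W|$ that an
uncorrected normal tail badly underestimates; the property tests verify
agreement with the exhaustive permutation oracle within 0.05 for
continuous data at total n ≤ 12. Under heavy integer-day ties at very
small n no normal approximation is trustworthy; that regime is what
`method = "exact_permutation"` is for, which enumerates all assignments
(practical to total n ≈ 20). Pairwise group comparisons default to no
multiplicity adjustment — matching how pairwise generalized-Wilcoxon
tables are conventionally reported in this literature — with Holm
available as an option.

## The synthetic generator

`simulation_config()` defines a complete generative model: demographics
(sex/age-band mix with configurable missingness), a pattern prevalence
vector over the eight combinations, a logistic AKI model (baseline
probability, per-pattern odds multiplier, covariate log-odds), and
per-group Weibull onset distributions. Its defaults are a *paper-mimic*
configuration echoing published JADER results for this question: pattern
prevalences follow the observed non-AKI report distribution, the baseline
AKI probability is the no-TW stratum's (~2.7%), the odds multipliers are
the published adjusted RORs (1.43, 1.76, 1.18, 2.41, 1.55, 1.70, 2.44),
and onset distributions are keyed by *(pattern, last-started class)* with
shapes around 0.5 and scales back-solved from the published KM medians via
$\lambda = m/(\ln 2)^{1/k}$. Keying by last-started class, not pattern
alone, is essential: within the RASI+NSAID pattern the published medians
are 7 days when the NSAID came last versus 119 days when the RASI came
last, a structure a per-pattern generator cannot express. Two medians
(RASI alone, diuretic alone) are not printed and were fixed once at 66 and
60 days, consistent with the published statement that they exceed 60 days.
Covariate log-odds (male 0.25, elderly 0.6, AKI-risk drug 0.7, year 0.01)
are plausible pharmacovigilance effect sizes chosen once; they are not
published values.

Two numerical conventions worth knowing:

* durations are floored to whole days (dates have daily resolution), and
  the continuous Weibull is parameterised so its median falls at the day
  midpoint $m + 0.5$; flooring then leaves the day-resolution median at
  the configured integer $m$ rather than flipping between $m-1$ and $m$;
* start orders are a uniform random permutation with exponential gaps
  (mean 60 days) between successive class starts; with a configurable
  probability all starts coincide, exercising the simultaneous-start
  exclusion.

What the generator does *not* emulate: correlated co-prescription
(patterns are drawn independently of covariates), duplicate or updated
reports of one case, brand-name noise in drug names, and calendar trends
other than a linear year effect on reporting odds. Passing tests therefore
demonstrate that the statistical machinery recovers known structure from
realistically shaped tables — not that real JADER extraction issues
(deduplication, name mapping) are solved.

## Problem sizes and determinism

The test suite runs recovery checks at moderate sizes chosen to keep the
default run fast while leaving comfortable statistical margins: Weibull
recovery sweeps at n = 2,000 across 20 seeds, prevalence recovery at
n = 10,000, crude-ROR recovery at n = 200,000, adjusted-ROR recovery at
n = 50,000. The acceptance script uses a 2.4-million-case paper-mimic database
for the disproportionality stage and a 300,000-case target-case simulation
(pattern mix following the published target-case composition, complete
dates) for the onset stage, giving every order stratum enough cases that
a single-run median is stable to about a day. Every random quantity flows
from one user-supplied seed; the pipeline consumes no wall-clock time or
machine identity, and two runs with the same seed produce byte-identical
output bundles.

## Known limitations

* Durations are whole days, but the Weibull likelihood is continuous;
  fitting day-floored data biases the shape estimate slightly upward for
  groups whose time scale is only a few days (the effect interacts with
  the zero-duration policy, since those groups also carry day-0 events).
  Shape estimates for short-onset groups should be read with that in
  mind; the effect is negligible for groups with medians of weeks or
  months.
* The shape-CI construction (Wald on log-shape from observed information)
  is one of several defensible choices; published CIs computed by other
  software may differ slightly in the second decimal even when point
  estimates agree.
* The deposited per-case duration dataset that published analyses of this
  question ship as supplementary material can be dropped in as
  `inst/extdata/tw_onset_durations.csv` (or `.xlsx` with `readxl`); the
  acceptance tests that reproduce published medians and shape estimates
  run against it and fail informatively when it is absent.
* `read_onset_dataset()` matches columns by tolerant header patterns;
  unusual supplementary layouts may need an explicit rename before
  loading.
* With only decade age bands, "age ≥ 70" is the only elderly definition
  expressible; no continuous-age analysis is possible.
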