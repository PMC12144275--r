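---
title: "Hourly-adjusted urine output and KDIGO-UO staging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hourly-adjusted urine output and KDIGO-UO staging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uoaki)
```

## The model

ICU urine output is not observed continuously. Urine accumulates in a
physical compartment — the bladder (drained by a Foley, straight or
suprapubic catheter, condom catheter, or voided spontaneously), a left or
right nephrostomy, or an ileal conduit — and a volume is charted whenever
the compartment is emptied. The package's generative picture is therefore a
set of *collection intervals*: within one compartment, the volume charted
at time $t_k$ accumulated over $(t_{k-1}, t_k]$, where $t_{k-1}$ is the
previous record in the *same* compartment, and carries a constant rate
$r_k = V_k / (t_k - t_{k-1})$ in ml/hr. Three consequences follow:

* the first record of a compartment has no known start — it is residual
  volume from before monitoring, dropped and used only as the timing
  anchor of the first real interval;
* compartments are sequential internally but parallel to each other, so
  rates add *across* compartments but never within one;
* an implausibly long gap (default more than 24 h) indicates a monitoring
  break rather than a 24-hour collection, so the interval is discarded.

The *hourly-adjusted UO* of a clock-aligned hour $h$ is
$\mathrm{UO}(h) = \sum_i r_i \, |I_i \cap h|$. Coverage of the hour is the
Lebesgue measure of $\bigcup_i I_i \cap h$ divided by one hour — a union,
so a second compartment covering the same minutes raises the value but not
the coverage. An hour is **valid** when coverage exceeds 0.5 strictly:
"most of the hour" is read as a strict majority (exactly 30 minutes does
not qualify), and the value is *never* rescaled by coverage — no
extrapolation into uncovered minutes, the validity flag does the work.
Both choices are deliberately conservative and reproducible; the threshold
is exposed (`coverage_threshold`) because the boundary convention is a
judgment call.

All timestamps are floored to whole minutes (charting is minute-granular in
the source systems) and overlap arithmetic is integer-minute, so
hour-boundary comparisons have no floating-point ambiguity.

## Staging

With $u(t)$ the valid per-kg series (ml/kg/hr, weight from the admission
record), the KDIGO-UO stage at hour $t$ is evaluated from trailing windows
of $w = 6, 12, 24$ hours. A window is *computable* only when every one of
its hours is valid and clock-consecutive; hence the first stage of an
admission exists after its sixth complete hour. Two customary readings of
the criteria differ in the window statistic $S_w$:

* **UO^mean** — $S_w$ is the running mean;
* **UO^cons** — every consecutive hour must be below threshold, i.e.
  $S_w$ is the window maximum.

The precedence ladder, with strict comparisons throughout: stage 3 if the
24-h window is computable and $S_{24} < 0.3$, or if 12 trailing hours are
exactly 0 (anuria; volumes are ml-granular, so exact equality with no
epsilon is appropriate); else stage 2 if $S_{12} < 0.5$; else stage 1 if
$S_6 < 0.5$; else stage 0. When only the 6-h window is computable, stages
2–3 are simply unavailable that hour — the complete-window requirement is
per window. Since a window maximum below threshold implies the mean below
threshold, UO^cons ≤ UO^mean pointwise; the test suite asserts this
dominance on randomized series alongside equality with a brute-force
per-hour window scan.

The numeric thresholds (0.5 and 0.3 ml/kg/hr; 6/12/24 h windows; 12-h
anuria) are configuration with guideline defaults (`kdigo_thresholds()`),
not constants, because sensitivity analyses on the window and outlier
parameters are a normal part of this literature.

The per-admission stratifier is the **peak stage** over computable hours
within 72 h of the first UO record, with an `at_admission` flag when the
earliest computable hour already stages ≥ 1 — AKI that may have begun
before ICU arrival. An admission with no computable hour in the horizon has
an undefined peak and is excluded from the AKI cohort (and counted).

## Cleaning and eligibility

Volumes outside $[0, 5000]$ ml are charting artifacts and removed
(zero-volume records are *legal*: true anuria is charted as 0 ml and makes
up roughly 1–2.5% of real charting). Admission weights outside
$[25, 300]$ kg are artifacts and exclude the whole stay. Labels that make
volumes untrustworthy as urine production (urethral stent, genitourinary
irrigation, urinary leak) exclude the admission outright — applied
uniformly at the admission level for every dialect, since the record-level
alternative would leave the remaining records of such admissions under
suspicion anyway. Unknown source labels fail hard by default: the label
vocabulary is small and enumerable, and silent dropping is how charting
pipelines go quietly wrong. Records timestamped outside the ICU stay are
excluded (a configurable grace period defaults to 0 h). AKI analysis
requires a usable weight, at least six consecutive valid hours, and the
patient's first ICU admission (to avoid repeated measures per survival
outcome); repeat stays remain processable for descriptive hourly UO.

Systems that store age and weight as 10-unit range groups are expanded to
group midpoints, with open-ended tail groups taking the tail value plus 5
units.

## Cohort statistics

30-day mortality is death within 30 days of ICU admission; follow-up is
capped at 30 days. Unadjusted odds ratios come from per-stage 2×2 tables
with Woolf (log-OR normal) intervals and no continuity correction — a zero
cell yields an explicit `NA` rather than a corrected estimate.

"Adjusted OR as a marginal effect" is under-specified in common usage, so
the package commits to g-computation: fit one logistic model of death on
stage (categorical), age, weight, gender and the at-admission flag with
stage × covariate interactions; for each stage $s$, set every admission to
stage $s$, average the predicted probabilities, and express the contrast
with stage 0 as an odds ratio. Confidence intervals are a seeded
nonparametric bootstrap over admissions (default 500 resamples). One
deliberate deviation from the "interact everything with stage" default:
the at-admission flag enters as a main effect only, because
`at_admission = TRUE` is structurally impossible at stage 0 — the
interaction is aliased and its "estimate" would be an artifact of how the
fitter resolves rank deficiency. The flag's interaction can be requested
explicitly (`interact_at_admission = TRUE`) for datasets where the nesting
does not hold.

Survival curves are product-limit estimates (via the `survival` package)
with administrative censoring at 30 days and pairwise log-rank tests per
stage pair. Stratified summary tables choose the between-group test per
declared column kind — chi-square (Fisher when any expected cell is below
5), one-way ANOVA, or Kruskal–Wallis — and report a conventional p of 1
for zero-variance columns instead of floating-point noise.

## The synthetic generator: what it emulates, and what it does not

`simulate_cohort()` produces cohorts whose defaults mirror the descriptive
behaviour of large ICU charting systems: a log-normal per-patient baseline
rate with median 85 ml/hr (the weighted-mean both-kidney rate observed in
such systems) with hour-to-hour log-normal noise; Foley-dominated source
mix with mostly exact hourly emptying; right-skewed voiding and
nephrostomy intervals (mode ≈ 120 min, median ≈ 180 min) and long
straight-cath intervals (mode ≈ 360, median ≈ 409 min); nephrostomy
patients carrying two single-kidney trajectories at ~51/49% of the
bladder-equivalent rate; oliguria episodes with configurable onset, depth
(ml/kg/hr) and duration, a fraction of which are anuric — which is also
what produces zero-volume records at a realistic 1–2.5% rate; a logistic
30-day mortality model in the true peak stage (default stage ORs 1.75,
3.31, 7.48 over a 7% baseline, anchoring to the published derivation-cohort
gradient); and a mild weight→oliguria association so that staging
covaries with weight as it does in real cohorts.

Two structural choices make ground truth analytic: the true rate is
piecewise-constant per clock hour, so charted volumes are *exact* integrals
of the truth over each collection interval, and ICU admission times are
hour-aligned, so `charting_mode = "hourly"` reproduces true hourly volumes
exactly and pipeline staging must equal truth staging hour for hour. The
truth stager is a separate vectorized implementation (shifted-matrix
rolling statistics), distinct from the pipeline's rolling-window path and
from the test suite's per-hour scan oracle, giving three independent
routes to the same quantity.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: charted volumes are not rounded to whole ml
(real charting is integer-ml, which adds bounded rounding error the exact
tests would otherwise absorb); there is no circadian or treatment-response
structure in the rate; charting times are independent of the rate, whereas
real nurses chart low-output patients differently (the prolonged-duration-
at-low-rate pattern); no missing weights, transfers, or documentation
gaps beyond what sparse charting induces. Pipeline correctness on these
cohorts demonstrates the *algebra* of the method, not the epidemiology of
any real ICU.

`inject_artifacts()` deterministically plants the pathologies the cleaning
rules target — out-of-range volumes, artifact weights, duplicate
simultaneous rows, admission-excluding labels — and returns a manifest, so
closure tests can verify each artifact is removed by exactly the intended
rule and nothing legitimate is touched.

## Numerical and degenerate-input choices

* Interval overlap and coverage arithmetic in integer minutes; equality at
  hour boundaries is exact, tolerance questions do not arise.
* Half-open intervals $(start, end]$ and hours $[HH{:}00, HH{+}1{:}00)$,
  so adjacent intervals never double-count a minute.
* Simultaneous same-compartment entries are summed *before* interval
  construction; a non-positive duration after merging is an internal error,
  not data.
* Empty inputs flow through: an empty records table yields empty hourly,
  staging and cohort tables with a zero-count flow ledger, not an error.
* The trailing 7-day creatinine baseline includes the measurement itself,
  so a monotone-decreasing series has zero change at every point (each
  value is its own window minimum); `include_current = FALSE` gives the
  open-window variant in which the first measurement has no baseline.
* Problem sizes in the checks were chosen to keep each property
  demonstrably tight yet quick: 500 random layouts against the
  minute-discretization oracle, 1,000 random 48-h series against the
  staging scan, 250 admissions for exact end-to-end recovery, 20,000 for
  mortality-model recovery (where OR precision needs event counts).

## Known limitations

* The duration-from-previous-record reconstruction is an assumption, not
  an observation; where a unit charts cumulative rather than emptied
  volumes the model does not apply.
* Coverage-based validity discards information in sparsely charted
  admissions rather than imputing it; that is the point of the method, but
  it means valid-hour coverage is a property of charting practice, not of
  the patient.
* The adjusted-OR model assumes the logistic form and the declared
  interaction set; the bootstrap quantifies sampling noise, not model
  misspecification.
* With hospital-mortality-only data sources, post-discharge deaths within
  30 days are unobservable; such cohorts censor at discharge and the
  cohort builder flags this in its output conventions.
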