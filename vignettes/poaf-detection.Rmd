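---
title: "Detecting postoperative atrial fibrillation from discharge abstracts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting postoperative atrial fibrillation from discharge abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poafr)
```

## The problem

New-onset atrial fibrillation after cardiac surgery (POAF) is a common and
costly complication. Measuring its incidence at scale is hard because the
reference standard — manual chart review — does not scale, while hospital
administrative data (discharge abstracts with ICD-10-CA diagnosis codes and
CCI procedure codes) are cheap and ubiquitous but were never designed for
incident-event detection. The central difficulty is distinguishing *new*
AF from *prevalent* AF: a discharge abstract carrying an AF code after
cardiac surgery may reflect either. `poafr` implements a family of
rule-based detection algorithms that resolve this with a multi-year
look-back over the patient's prior hospitalizations, and the complete
statistical machinery needed to validate such algorithms against chart
review.

## The detection rule

An index cardiac-surgery hospitalization is classified POAF-positive when
all of the following hold:

1. **Flag**: a flag code — by default I48.0 (paroxysmal AF), I48.1
   (persistent AF), I48.9 (AF/flutter, unspecified) or I48.90 (AF,
   unspecified) — appears in *any* diagnosis position of the index
   abstract. Position is not restricted by default because coding depth
   varies by hospital and the principal-diagnosis slot is usually taken
   by the surgical indication; `diagnosis_positions = "principal"`
   restricts the rule to the principal slot.
2. **No history**: no history code — the flag codes plus I48.2 (chronic
   AF) — appears on any hospitalization of the same patient discharged
   within the look-back window (1, 3 or 6 years) before the index
   admission. I48.2 is history-only: chronic AF on the *index* abstract
   cannot be dated within the stay, so it neither flags POAF nor counts as
   history. This is a deliberate fidelity choice: administrative data
   cannot time-stamp diagnoses inside a hospitalization, and that
   limitation is part of what a validation study measures.
3. **No maze** (variants with `maze_recode = TRUE` only): no concomitant
   maze procedure (CCI 1.HH.59). The maze operation is surgical ablation
   of chronic AF, so its presence implies pre-existing AF; such patients
   are recoded negative even when their diagnosis codes suggest POAF.

`standard_algorithms()` enumerates the six standard variants (three
windows × maze recode on/off); `restricted_code_variant()` drops the
unspecified codes I48.9/I48.90 from the flag set for sensitivity analyses.
I48.9 is retained in the default flag set even though real Canadian data
rarely use it — the rule is specified over the full unspecified-AF family.

Two look-back conventions were genuinely open and are exposed as options:

* **Anchor**: the window ends at the index *admission* date (default), not
  the surgery date. A diagnosis code attaches to a completed
  hospitalization, and anchoring on admission guarantees the index stay
  can never contribute to its own history.
* **Membership**: a prior hospitalization is in the window when its
  *discharge* date (`lookback_on = "discharge"`; the admission-date
  convention is the alternative) falls in the half-open interval
  `[anchor − w years, anchor)`. The half-open boundary makes windows nest
  exactly (1 ⊆ 3 ⊆ 6 years), which in turn yields the monotonicity
  property the tests verify: lengthening the window can only turn
  predictions negative, never positive.

When a patient has several eligible surgeries in the study window, the
first is the index case and later ones are ignored.

## Accuracy statistics

Validation against a chart-review reference standard produces a 2×2 table
per algorithm; `accuracy_metrics()` reports sensitivity, specificity, PPV
and NPV, each as a binomial proportion on its own denominator. Choices
that matter:

* **Confidence intervals** are Clopper-Pearson exact by default
  (`qbeta` inversion of the binomial tails). The exact interval, not the
  Wilson score interval, reproduces published validation tables of this
  kind to the printed decimal (e.g. 228/324 gives 65.1–75.3 exactly,
  where Wilson gives 65.2–75.1); Wilson remains available via
  `method = "wilson"`.
* **Undefined metrics** (zero denominator, e.g. PPV of an algorithm that
  flags nobody) are reported as `NA` with an explicit `undefined` flag —
  never as 0 and never dropped silently.
* **Rounding** for display is half-up to one decimal on the percentage
  scale, matching the convention of published accuracy tables. (Base R's
  `round()` is banker's rounding, which would disagree on exact .05
  boundaries.)

**Paired algorithm comparisons.** Two algorithms applied to the same
patients are compared on sensitivity/specificity with McNemar's test
(uncorrected χ² by default; continuity-corrected and exact-binomial
variants by flag; no discordance reported as p = 1 with a flag).
Predictive values cannot be McNemar-compared because the conditioning sets
(who tests positive) differ between algorithms; `leisenring_pv_test()`
implements the generalized score statistic for paired predictive values:
stack one record per (subject, algorithm) restricted to test-positive
(PPV) or test-negative (NPV) records, fit the common predictive value
under the null, and test the algorithm indicator with a score whose
variance is summed over subject clusters, referred to χ²₁. The test suite
checks this implementation two ways: against an independently coded
matrix-algebra evaluation of the score and cluster-sandwich variance, and
by Monte-Carlo type-I error under a simulated null (two equally accurate,
conditionally independent tests; rejection rate at α = 0.05 inside the
binomial band for 2,000 replicates).

**Between-site comparisons.** Sites enrol disjoint patients, so no paired
structure exists and a literal McNemar test is undefined. `compare_sites()`
therefore uses the unpaired two-sample pooled score (z) test on each
metric's own numerator and denominator (Fisher's exact by flag). This is a
documented divergence from validation reports that describe site contrasts
with "McNemar's test": with disjoint patients that computation is not
recoverable, and the unpaired test is the defensible substitute. Its
significance calls agree qualitatively with the published site pattern
(sensitivity and NPV differ between sites; specificity and PPV do not).

**Multiplicity.** Bonferroni correction with `m` defaulting to the number
of pairwise comparisons actually performed per metric family; overridable
because the appropriate family is a judgement call.

**Table inversion.** `invert_rounded_table()` exhaustively searches the
integer grid `(tp, tn)` for matrices whose four recomputed metrics round
half-up to a printed row, given the reference positive/negative
denominators. Published rows of the size handled here (hundreds per arm)
almost always pin a unique matrix, which makes printed tables exactly
re-checkable; multiple solutions are returned with a warning, none is an
error.

## The synthetic world

`simulate_cohort()` generates a longitudinal discharge-abstract world with
known truth so the whole pipeline is testable without access to real
hospital data. Per patient: site, surgery class and date; latent chronic
AF (`H`); latent POAF (`D`, possible only when `H = 0`; the reference
standard is positive iff `D = 1`); maze procedures among chronic-AF
patients; Poisson-count prior hospitalizations with discharge dates
uniform over the 6-year horizon; then observed codes through a per-site
`coding_model()` with independent coding events. Configured POAF
incidences are on the all-patients scale and are divided by `1 − h`
internally, so the observed reference-positive rate matches the
configuration directly.

Defaults are the study conditions of a two-centre cardiac-surgery
validation cohort: site weights 0.49/0.51; per-site surgery mixes
(CABG/valvular/mixed ≈ 0.42/0.31/0.27 and 0.52/0.29/0.20) and per-class
POAF incidences chosen so the pooled incidence is ≈ 33.2% (36.3% at site
A, 30.2% at site B); maze in ≈ 3.2% of patients (chronic-AF prevalence
0.10 × maze-given-chronic 0.32). The coding rates are *illustrative*, not
estimable from any published source: site A codes a true POAF episode
with probability 0.64 and site B with 0.80, which reproduces the observed
qualitative site effect (sensitivity and NPV depressed at the
under-coding site, specificity and PPV roughly stable); false flag codes
at 0.08–0.10 absorb both miscoding and coded transient AF (transient
POAF is reference-negative); chronic AF is coded on the index abstract
with probability 0.6 and on each prior hospitalization with 0.5; spurious
AF history codes arise at 0.01 per prior hospitalization; prior
hospitalizations average 0.8 per patient over 6 years, consistent with a
median of zero in the year before surgery. These values were fixed once
from the marginal rates above and are not tuning knobs.

Because every coding event is independent given the latent state and
in-window prior counts are Poisson, the four accuracy metrics have closed
forms (`expected_accuracy()`): with window fraction `f = w/6` and prior
rate λ,

* sensitivity = `p_code_given_poaf · exp(−λf · p_false_history)`;
* the false-positive rate mixes the chronic stratum
  (`p_code_given_chronic · exp(−λf · p_history) ·
  (1 − maze_given_chronic)` when maze recoding is on) with the no-AF
  stratum (`p_false_code · exp(−λf · p_false_history)`), weighted by the
  stratum prevalences;
* PPV and NPV follow from Bayes' rule at the configured prevalence.

The tests verify these closed forms against simulation at n = 50,000
(within three Monte-Carlo standard errors), which is the module's central
correctness property: the generator, the detection rule and the analytic
model must agree with each other.

What the generator does **not** emulate: realistic ICD co-occurrence and
comorbidity profiles, lengths of stay beyond what date linkage needs,
coding drift over calendar time, POAF among chronic-AF patients
(excluded by the reference-standard definition), and maze procedures in
patients without documented chronic AF. Passing tests therefore show the
pipeline is internally correct and calibrated under this generative
model — they do not show that real hospitals code this way, and measured
accuracies on real data can differ materially (that is precisely what a
local validation would quantify).

## Numerical and interface choices

* All randomness in a simulation flows from a single `set.seed()` call
  through one sequential RNG stream in a fixed draw order, so equal seeds
  give byte-identical output files.
* `select_best()` breaks ties deterministically: fewest look-back years,
  then list position; `prefer_longest_lookback = TRUE` flips the first
  tie-break for users who prefer the stronger prevalent-AF exclusion at
  equal sensitivity.
* Codes are normalized on ingest (upper-case, dots stripped, wildcard
  runs collapsed to one `^`); unknown codes are kept verbatim — they
  simply never match a code set — because administrative extracts always
  contain codes outside the study universe.
* Degenerate inputs are explicit: empty look-back lists are valid (no
  history), empty prediction sets make predictive-value comparisons an
  error rather than a silent zero, and exclusion bookkeeping must
  partition the roster exactly.
* Problem sizes used by the test suite — 1,000 randomized cases for the
  brute-force classification oracle, 2,000 null replicates at n = 500 for
  test calibration, n = 50,000 for simulation-vs-closed-form agreement,
  2,000 draws per cell for interval coverage — were chosen as the
  smallest sizes at which the Monte-Carlo bands are meaningfully tight.

## Known limitations

* The detection rule can only see hospitalizations present in the data:
  AF documented at outside institutions, in clinics, or only in narrative
  notes is invisible, which bounds achievable sensitivity.
* The look-back conventions (admission anchor, discharge-date membership)
  are defensible but not uniquely determined; both alternatives are
  exposed as configuration.
* The generalized score test is asymptotic; at very small numbers of
  test-positives its calibration degrades, and the package does not
  currently offer an exact alternative for predictive values.
* The synthetic coding model is deliberately simple (independent events,
  one flag-code family); it is a test harness, not an epidemiological
  model of coding behaviour.
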