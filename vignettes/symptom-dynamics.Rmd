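---
title: "Modelling antidepressant symptom dynamics with stratified trajectories"
author: "symptomPGM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling antidepressant symptom dynamics with stratified trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomPGM)
```

## The problem

Antidepressant response is heterogeneous: patients who begin treatment with
the same total depression severity diverge into remission, response without
remission, or nonresponse by the end of a standard 8-week trial.  Clinical
decisions, however, have to be made earlier — typically around week 4.  The
question this package operationalises is: *which individual depressive
symptoms, and what magnitude of change in them by week 4, predict the 8-week
outcome?*

The data are 17-item Hamilton Depression Rating Scale (HDRS-17) assessments
at baseline, week 4 and week 8 — one severity score of 0–4 (or 0–2 for the
milder items) per symptom, summing to a total of 0–52.  Outcomes follow the
standard conventions: remission is a week-8 total of at most 7; response is a
reduction of more than 50% from baseline with a total above 7; everything
else is nonresponse.  A reduction of exactly 50% is classified nonresponse —
"response" is kept strictly greater than half, the conservative reading of
the usual ">50%" definition.

## The model

The pipeline has four stages.

**1. Severity stratification.**  At each timepoint, total scores are
modelled as a univariate Gaussian mixture with unequal component variances.
The number of components is chosen by BIC over `k = 1..6`, with ties broken
toward the smaller `k`, so the model is the *minimum* number of strata that
describes the score distribution.  Fitting is delegated to the `mclust`
package, whose hierarchical-EM initialisation is deterministic: a fixed data
set always yields the same fit, and no random restarts are needed.  If EM
degenerates at some `k` (spiked components on the integer score grid),
that `k` is simply dropped from the BIC comparison.

Patients are assigned to the component whose *unweighted* Gaussian density
at their score is maximal — only the learned means and standard deviations
enter the assignment, not the mixing weights.  The weighted-posterior
alternative is available behind `use_weights = TRUE`.  On the observed score
range, assignment by maximal density with ascending means is monotone in the
total, so each stratum owns a contiguous score interval; `derive_ranges()`
records these empirical `[min, max]` ranges and verifies their disjointness.
(Far outside the observed range the widest component's tails dominate and
max-density assignment is no longer monotone — this is why monotonicity is
checked on the observed range, not the whole 0–52 line.)

**2. Trajectories.**  With `N` strata at each of `t` timepoints there are
`N^t` candidate trajectories (27 for the default 3 × 3).  A hidden Markov
model with forward transitions links the strata: transition probabilities
are the fractions of patients moving between strata of consecutive
timepoints, and each path's likelihood, conditional on its baseline stratum,
is computed by the forward recursion (strata are directly observed, so the
emission matrix is the identity and the recursion reduces to the product of
forward transition probabilities — it is retained in its general form so
more timepoints slot in unchanged, and it is oracle-tested against explicit
product enumeration).  For every (baseline, week-8) stratum pair, the
maximum-likelihood path carrying at least 10% of the baseline stratum's
patients is selected as a *symptom dynamic path*; pairs with no qualifying
path yield none.  Likelihood ties break toward the larger patient fraction,
then toward the less severe week-4 stratum.

**3. Prognostic-symptom mining.**  A symptom is prognostic when it passes
three criteria:

* *(a) Baseline presence.*  Strictly more than half of the patients score it
  above zero at baseline.  An absent symptom cannot carry a measurable early
  reduction.
* *(b) Grouping.*  Along every selected path and at every timepoint, at
  least one other symptom's median severity lies within one scale point of
  the item's own median among the path's patients.  This is the
  level-similarity reading of symptom clustering: prognostic symptoms move
  as a group, not as isolated outliers.  A hard dendrogram cut
  (`cluster_symptoms()` exposes one per stratum for inspection) proved
  unstable in low-severity strata, where all items compress toward zero and
  cluster boundaries are noise; the nearest-companion criterion is stable
  there and captures the same idea.
* *(c) Discrimination.*  The item's dynamics must differ between paths
  *beyond what the total score implies*.  This qualifier is essential:
  paths are defined by total-score strata, so the raw severity of every
  item differs across paths mechanically — a patient whose total halves
  improves on most items.  Any test on raw item severities would flag all
  17 items, including in a placebo arm.  The statistic used instead is the
  **relative change standing**: for each patient, an item is compared only
  to its severity-matched peers — the patient's other items with the same
  baseline score and the same item maximum — and scored by the midrank
  proportion of peers whose improvement it exceeds.  When an item carries
  no information beyond the total, matched items are exchangeable and the
  standing has expectation 1/2 whatever the trajectory; this holds exactly,
  with no distributional assumptions, which is what makes the placebo
  negative control meaningful.  Standings (at week 4 and week 8) are
  compared across path-endpoint groups with Welch's one-way ANOVA, the two
  timepoints combined by Fisher's method, and the 17 items Holm-corrected
  at `alpha = 0.05`.  Finally a direction gate requires the item's standing
  to *decrease* with endpoint severity — prognostic symptoms improve more
  than their peers along remitting paths.  The gate also neutralises a
  subtle artefact: a null item whose matched peers happen to include
  genuinely prognostic items inherits a mirror image of their signal, with
  the opposite sign.

An empty mined set is a legal and meaningful result — it is the expected
outcome on placebo data.

**4. Prognosis rules.**  For each (baseline stratum, week-4 stratum)
transition appearing in the selected paths, a rule of the form

> if at least *m* of the prognostic symptoms change by *delta* points by
> week 4, predict *outcome*

is derived.  The predicted outcome is the modal observed 8-week outcome
among patients making the transition (ties toward the more severe outcome).
This matters for mildly depressed patients: a mild baseline with an
unchanged week-4 total often ends in the middle week-8 stratum, whose
*score range* looks like response but whose patients have lost less than
half their baseline total — the observed outcomes, not the stratum label,
decide.  The threshold *delta* is the rounded median, over prognostic items,
of the absolute difference between median baseline and median week-4 scores
among the path's patients, floored at one point; its direction is "improved
by at least delta" for remission/response rules and "improved by at most
delta" (which includes worsening) for nonresponse rules.  The minimum count
*m* is the smallest count whose 2×2 association with the predicted outcome
is chi-square significant (Yates-corrected) *and positive* — the screen is
direction-aware because a count can also associate negatively (in a
moderate-improvement transition the strongest improvers may be
remission-bound rather than response-bound, and a direction-blind screen
happily selects that inverted split).  Rules from the same baseline stratum
with the same outcome, direction and threshold are merged, pooling their
week-4 strata ("B2 or B3" rules).

Each rule is evaluated on the patients making its transition: coverage
(fraction meeting the count condition), accuracy (fraction of covered
patients with the predicted outcome), the covered-vs-uncovered odds ratio
with Haldane–Anscombe 0.5-correction when a cell is empty and a Woolf
log-normal 95% CI, and a one-sided exact binomial test of the accuracy
against the null information rate (NIR).  The NIR ships as the constant
0.53 — a reported benchmark accuracy achievable from baseline clinical and
sociodemographic predictors alone — and is overridable.

**Replication** freezes everything: test-cohort patients are assigned to
strata by looking their totals up in the *training* score ranges (totals
falling outside every range snap to the nearest boundary's stratum, with a
warning, so every test patient is assignable), and the frozen rules are
re-evaluated with no parameter changes.  Kolmogorov–Smirnov (age) and
chi-square (sex, race) tests check that rule coverage and correctness are
not demographically structured.

## The synthetic cohort generator

No suitable clinical HDRS cohorts are publicly deposited, so the package
ships a generator that emulates the statistical structure the analysis
assumes, with a planted, switchable item-level signal:

* **Latent strata and totals.**  Each patient draws a stratum sequence from
  baseline weights and two row-stochastic forward transition matrices, then
  a total score at each timepoint from the stratum's Gaussian, rejected
  into the stratum's score range and rounded.  Default ranges are the
  reference stratifications (baseline 14–18 / 19–24 / 25–39; week 4 0–8 /
  9–15 / 16–31; week 8 0–7 / 8–15 / 16–34); default means are range
  midpoints and default SDs range-width/6, so the mixture is well separated
  at every timepoint.  Default baseline weights (0.30, 0.37, 0.33) spread
  patients across severities, and the default transitions make the
  "diagonal" remission/response/nonresponse paths dominant, give the
  mild-baseline stratum essentially no 10% path into the most severe
  endpoint, and give the moderate week-4 stratum a response-dominated
  endpoint mix — the qualitative shape reported for antidepressant trial cohorts.
* **Item decomposition.**  Totals are decomposed into 17 item scores by a
  capacity-respecting *systematic allocation*: each item receives the
  integer part of its proportional share and the leftover points are
  sampled with probability proportional to the fractional parts.  The
  allocation is unbiased up to the item caps — an item's expected score is
  proportional to its allocation weight — and adds less than one point of
  rounding noise.  Baseline weights are proportional to item maxima with a
  mild 1.3× up-weight for the prognostic items (prominent presenting
  complaints that still overlap the other items' severity range); weights
  are jittered log-normally (`noise_sd`, default 0.3) for inter-patient
  profile heterogeneity.  At follow-ups each item's weight is its realised
  baseline score times the patient's total-score ratio — *proportional
  dynamics*, under which no item carries path information beyond the total
  and the severity-matched exchangeability that criterion (c) tests holds
  exactly.
* **The planted signal.**  In the drug arm, the prognostic items' follow-up
  scale is blended by `coupling_strength` (default 0.75) toward a
  path-determined trajectory: near-complete resolution (2%/1% of baseline)
  on paths ending in the remission-range stratum, halving on middle paths,
  and flat (100%/95%) on nonresponding paths.  This is the planted signal
  the mining stage must find; with the defaults, the prognostic items'
  median raw 4-week improvement differs by at least 2 points between
  patients whose paths end in the least vs most severe stratum.  In the
  placebo arm the coupling is forced to zero, so the mined set should be
  empty.
* **Demographics** (age, sex, race) are generated independently of
  everything else, making the demographic association tests null by
  construction.
* **Determinism.**  Every patient draws from a substream derived from
  (seed, patient index), so cohorts are byte-reproducible and invariant to
  generation order.

What the generator does *not* emulate — and hence what passing tests do not
establish about clinical data: dropout and missing visits (records are
complete by construction), item-level clinical structure beyond severity
levels and the planted coupling (no somatic/psychic factor structure, no
floor effects from sparse items), dose effects, comorbidity, site effects,
or any correlation between demographics and response.  The generator
validates the *machinery*; claims about real cohorts need real cohorts.

## Numerical choices and edge cases

* BIC ties (within 1e-6) go to the smaller `k`; `k` values where EM
  degenerates are skipped; fitting fewer than `10 * max(k_range)` points is
  refused.
* Stratum-assignment ties go to the less severe label.  Path-selection
  ties: larger patient fraction, then less severe week-4 stratum.
  Modal-outcome ties: more severe outcome.
* Paths with fewer than 5 patients are dropped from mining comparisons
  (underpowered), and items with no severity-matched peer in a patient
  contribute `NA` standings that the tests drop.
* A rule whose minimum-count screen is fully degenerate (every transition
  patient already has the predicted outcome) falls back to `m = 1`,
  flagged — the screen carries no information there.
* Zero cells in any evaluated 2×2 table trigger the Haldane–Anscombe
  correction, keeping every odds ratio finite and positive.
* All artifacts serialize to JSON/CSV deterministically; re-running a
  training with the same seed reproduces byte-identical files.

## Problem sizes used in the test suite

The bundled tests run the full pipeline on synthetic cohorts of 1,800
patients (about 100–450 patients per selected path, comparable to the
per-transition counts reported for trial cohorts of this kind), use 900-point samples for the
mixture-recovery checks, 50,000 patients for the transition-frequency
self-test, and 2,000 patients for the end-to-end rule evaluation and
frozen-rule replication, with 20-seed batteries for the recovery-rate
properties.  These sizes keep the whole suite in the low minutes on a
single core while leaving each check well powered.

## Limitations

The pipeline inherits the design constraints of the three-timepoint trial
structure: it cannot say anything about earlier (week-2) prediction, about
trajectories past week 8, or about treatment selection after nonresponse.
The NIR is a fixed external comparator, not estimated from the data at
hand.  Criterion (c)'s matched-peer construction needs items sharing
baseline scores; on scales much sparser than the HDRS-17 the matched sets
would thin out.  And the mined symptom set is a property of the cohort
analysed — the package replicates *rules* across cohorts, not the mining
itself.
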