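---
title: "Methods: OLVF scoring, screening metrics, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OLVF scoring, screening metrics, and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olvfss)
```

## Scope and model

`olvfss` evaluates how well baseline assessments — DXA T-scores and
radiographic vertebral fractural-deformity scores — predict incident hip
fracture in sex-stratified community cohorts of older adults, using crude
(count-based) operating characteristics: positive predictive value (PPV),
detection sensitivity, incidence, and their ratio. Everything is descriptive:
no survival modelling, confidence intervals, or multiplicity adjustment, which
matches how such cohort screening comparisons are reported when event counts
are small (tens of fractures among thousands of subjects).

## eSQ grading

Each vertebra from T3 to L5 is graded by fractional height loss into six
severity subgrades (minimal, mild, moderate, moderately severe, severe,
collapsed) scoring −0.5 to −3 in steps of 0.5. Two conventions needed fixing
where the verbal definitions are ambiguous:

* **Interval edges.** All bands are closed on the left and open on the right
  (a loss of exactly 25% is moderate, not mild), and the conventional "33%" and
  "66%" bounds are taken as exactly 1/3 and 2/3. `esq_grade_table()` is the
  single authority used by the grader.
* **The minimal grade is a reader judgement.** Below 20% loss, a deformity is
  scored −0.5 only when flagged distinctly fracture-like *and* the measured
  loss is positive: a flagged shape change with literally zero measured loss
  is outside the quantitative model and scores 0. From 20% upward the grade
  follows the measurement alone.
* **Non-fracture causes dominate.** A deformity wholly attributed to
  osteoarthritic wedging or an endplatitis short vertebra scores 0 regardless
  of height loss; a fractural deformity co-existing with such changes is
  counted. These judgements enter as flags — the package does no image
  reading.

Height loss estimation (`estimate_height_loss`) compares the target's
anterior, middle and posterior heights (mm) with expected heights linearly
interpolated, per position, between the nearest morphologically normal
vertebrae above and below (carried from the single nearest normal level when
only one side has references). Linear interpolation in anatomical position is
the simplest symmetric choice consistent with "comparing with neighbouring
vertebrae of normal shape"; the loss reported is the maximum over the three
positions, floored at 0, since a fracture usually reduces one height most and
graders key on the worst one. Whether readers in practice use one or three
heights is not standardised; max-over-positions is our documented choice.

## The OLVF sum score

`compute_olvfss` sums per-vertebra scores over T3–L5 after two adjacency
adjustments, with adjacency meaning consecutive anatomical positions (T12–L1
included):

1. **Suppression** — a minimal (−0.5) vertebra adjacent to a vertebra scored
   ≤ −1.0 contributes nothing. (A minimal deformity next to a frank fracture
   is most plausibly collateral endplate change rather than an independent
   fracture.) The canonical example: T12 = −0.5 next to L1 = −2.0 scores
   −2.0 in total, not −2.5.
2. **Run merging** — each maximal run of k ≥ 2 *surviving* adjacent minimal
   vertebrae contributes −0.5·⌈k/2⌉: two adjacent minimals −0.5, three −1.0.
   Runs longer than three are not specified by the grading convention; the
   ⌈k/2⌉ extrapolation reproduces both stated cases and continues the
   half-weighting pattern.

Two ordering questions are open in the verbal rules and resolved here:
suppression is applied **before** run merging (a minimal flanked by a severe
vertebra on one side and a minimal on the other is suppressed first; the
surviving neighbours then merge). This order is the only one we found that
makes the suppression example and both run examples simultaneously
consistent. The severe-neighbour condition is a score of −1.0 or below (a
convention sometimes written with the sign dropped). The suite checks the implementation against
an independently written brute-force oracle on *every* spine with up to four
deformities (≈ 1.9 million spines) and on random deeper spines.

`most_severe_olvf` deliberately uses raw per-vertebra scores, not
post-adjustment contributions, because "most severe OLVF" thresholds describe
individual deformities. Levels outside T3–L5 are rejected, not ignored:
silently dropping a T2 score would change a sum the caller thinks they
supplied.

## Metrics and screening performance

Built-in cutpoints are sex-specific because fragility-fracture criteria for
men must be stricter (mild deformities are common in men with normal bone
strength) and T-score cutpoints are population- and site-specific: women
FN ≤ −2.7, LS ≤ −3.7 / −2.5, OLVFss ≤ −1.5, most-severe = −3.0 / ≤ −2.5; men
FN ≤ −2.1, LS ≤ −2.5, OLVFss ≤ −2.0 / −2.5 / −3.0, most-severe ≤ −2.0 /
≤ −2.5 / = −3.0. "Most severe = −3.0" is equality at the score floor, i.e.
identical to ≤ −3.0. Sexes are never pooled anywhere.

The analysis set for horizon *h* keeps subjects who fractured at t ≤ h or
survived to h, and excludes deaths before h without prior fracture — a
listwise rule, not person-time: it reproduces crude reported percentages
exactly, at the cost of ignoring partial follow-up of the excluded deaths.
The exclusion is horizon-specific (a death at 3.5 years is excluded at h = 5
but counted as a survivor at h = 3); published analyses sometimes reuse one
analysis set across horizons, so small denominator differences can appear.
Missing quantities (an unmeasured LS T-score) make a subject unevaluable for
that metric only and drop them from both numerator and denominator. Empty
denominators yield `NA` ("undefined"), never 0: a metric that flags nobody
has no PPV. Percentages print at 3 decimals (PPV, incidence) and 2
(sensitivity); raw counts are always retained alongside as "k/n" pairs.

## The synthetic cohort generator

A single latent standard-normal frailty Z per subject drives everything:

* T-scores: T = μ + σ(−ρZ + √(1−ρ²)ε), so `t_frailty_loading` ρ is the
  correlation between frailty and *low* BMD (default 0.7 for both sites).
* Deformity burden: count K ~ Poisson(λ₀·e^{γZ}) capped at 15, severities
  i.i.d. categorical (`severity_probs`), placed uniformly without collision
  over the 15 levels.
* Hip fracture within the horizon: Bernoulli(plogis(α + βZ)), event time
  uniform on (0, h]; death is independent of frailty (no death model is
  available to emulate) with probability `death_rate` and uniform time; a
  death drawn before the fracture time cancels the fracture, so records never
  contain a post-mortem event.

Uniform event times are adequate because all downstream statistics use only
cumulative counts at the analysed horizons. All randomness flows from one
seed through a local RNG stream (the global `.Random.seed` is untouched).

Defaults are the stated world of a community cohort of ~2000 Chinese women or
men aged ≥ 65 (mean ≈ 72.4): they were fixed once, before the test suite ran,
by matching the model-implied five-year characteristics to the cohort's
reference values — incidence 1.333% / 1.222% and FN-cutpoint positivity ≈ 16.7% /
15.0% capturing 65.4% / 52.2% of fracture cases (solving μ, α, β by
one-dimensional integration given ρ = 0.7 and σ = 1), and OLVF burden
(λ₀ = 0.195 / 0.28, γ = 1.1 / 0.85, severity mixes) matched by pilot
simulation to the reference OLVF-metric positivity counts (e.g. 92 of 1951
women with a collapsed vertebra) and sensitivities. `expected_summaries()`
recomputes the implied values at run time — closed-form conditional-normal
integration for T-score metrics, pilot simulation for OLVF metrics (the
adjacency rules have no useful closed form); its `path` column records which
route each metric used.

What the generator does **not** emulate: reader disagreement and flag noise
(scores arrive error-free), age as a separate risk factor (frailty absorbs
it; simulated age is decorative), frailty-dependent mortality, medication
effects, and any difference in informativeness between FN and LS BMD — one
loading serves both sites, so the simulated LS metrics are as predictive as
FN, unlike real cohorts where degenerative changes inflate LS BMD in the
elderly. A green simulation-based test therefore establishes internal
consistency of the pipeline and calibration, not clinical validity of LS
cutpoints.

## Numerical and degenerate-input conventions

* OLVFss lies in [−45, 0] in exact multiples of 0.5; scores are binary-exact
  halves, so no floating-point tolerance is needed in score arithmetic.
* An empty spine (no deformity rows) is valid and scores 0 / 0 / 0.
* `±Inf` cutpoints are accepted and behave as never/always positive; an
  always-positive metric's PPV equals the incidence and its risk ratio is 1.
* Fractures after death are rejected at input validation; horizon must be a
  single positive number.
* CSV is the only exchange format (UTF-8, header, "." decimals); pipeline and
  simulation configs are JSON (no YAML parser is assumed available).

## Known limitations

Crude ratios ignore censoring time, so the risk ratio is not a hazard ratio
and will differ from survival-based estimates on the same data. The fixture
route reproduces reference operating characteristics exactly but fixes joint
distributions the reference counts never constrain (e.g. which FN-positive subjects also
carry deformities) arbitrarily where unconstrained. At realistic cohort sizes
(~2000, ~25 events) all sensitivity estimates carry binomial noise of several
percentage points; single-seed simulated cohorts should be compared with
`expected_summaries()`, not with each other.
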