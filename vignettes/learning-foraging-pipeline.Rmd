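---
title: "Linking visual learning performance to lifetime foraging in bumble bees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking visual learning performance to lifetime foraging in bumble bees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeforage)
```

## The scientific question

Individual bumble bee (*Bombus terrestris*) workers differ markedly in how
fast they learn a colour/reward association in the laboratory. Does that
variation predict anything about their subsequent foraging careers in the
field? `beeforage` implements the full analysis chain needed to answer this
for a cohort of individually tagged workers:

1. **Learning performance** — each naive worker forages in an array of blue
   (unrewarding) and yellow (rewarding) artificial flowers while its choices
   over 100 sequential flower visits are recorded.
2. **Field activity** — the same workers are RFID-tagged and released to
   forage freely; a reader at the nest entrance logs every departure and
   return.
3. **Foraging efficiency** — on a sample of trips, a weighing station
   records the bee's mass on exit and return, plus an ordinal score of any
   pollen load.
4. **Inference** — mixed models with colony as a random intercept are
   compared by AICc to ask whether learning ability predicts five foraging
   responses.

Because no field data set of this shape is publicly deposited, the package
ships a seeded synthetic-cohort generator that emulates the joint structure
of all three data streams, so every stage is testable end to end and effect
recovery can be asserted quantitatively.

## The learning model

Errors (choices of blue flowers) decline with experience. With `x` the
number of choices made after the bee first feeds from ("probes") a yellow
flower, errors per 10-choice block are modelled by a first-order decay

$$y(x) = y_0 + A\,e^{-x/t},$$

where `y0` is the saturation error level (errors per block at the
performance plateau), `A` the curve amplitude and `t` the decay constant — a
measure of learning speed. The per-bee **Learning Performance Index (LPI)**
sums the curve's predictions after 5, 50 and 100 choices, clamping each
prediction to the attainable \[0, 10\] errors per block, so LPI lies in
\[0, 30\]. Low LPI = fast learner.

Fitting details that matter:

* **Alignment and binning.** Visits up to and including the first yellow
  probe are dropped; the remaining choices are cut into full blocks of 10
  and each block sits at its midpoint abscissa (5, 15, ..., 95). A trailing
  partial block is discarded. Sequences with no yellow probe, or fewer than
  three full blocks (too few points for three parameters), are flagged
  unfittable and excluded downstream — mirroring how a real assay can fail
  for an individual that performs too poorly to fit.
* **Optimisation.** Bounded Levenberg–Marquardt least squares
  (`minpack.lm::nlsLM`) with `y0` in \[0, 10\], `A` in \[-10, 10\] and `t`
  in (0, 10 × choices\]. Starting values are `y0` = mean of the last two
  blocks, `A` = first block − `y0`, and a multi-start grid `t0 ∈ {20, 5,
  80}`; the converged start with the lowest residual sum of squares wins.
* **Degenerate data.** Constant blocks admit a continuum of exact solutions;
  the smallest-|A| solution (`y0 = c`, `A = 0`, `t` stored as missing) is
  reported, and the LPI is still defined from `y0` alone.
* **LPI evaluation** uses the smooth fitted curve at 5, 50 and 100 choices
  (interpolation/extrapolation), not the raw block counts; clamping before
  summation is what guarantees the 0–30 range for any admissible parameters.

## From tag reads to foraging bouts

A foraging bout is one trip outside the nest: an "out" read paired with the
next "in" read for the same bee. Raw reader streams are messy, so
`clean_events()` applies a conservative repair: exact duplicates are
collapsed, and two consecutive same-direction reads imply a missed read —
the incomplete excursion is discarded rather than imputed (no invented
durations). Candidate bouts shorter than 2 minutes (configurable) are
treated as entrance-platform loitering and dropped; the shortest plausible
real trips are an order of magnitude longer. A final "out" with no return is
a censored departure, not a bout. Days are calendar dates of bout starts —
these bees do not fly at night, so bouts never span a day boundary.

Per bee, `summarize_activity()` yields the three activity responses: days
foraged (distinct dates with a bout), mean bouts per day (total bouts /
days foraged) and mean bout duration. A bee is a **forager** when it
completes more than five bouts.

## Collection rates

Weighing-station records are matched to bouts by nearest boundary within a
2-minute tolerance (stable earlier-bout tie-break; each record attaches to
at most one bout). A bout observed on both exit and return is classified by
its incoming record: any pollen load makes it a pollen bout, otherwise it is
a nectar bout. For bees with at least three observed bouts of a type:

* **nectar rate** = (mean incoming mass − mean outgoing mass) / mean bout
  duration, in mg/min, over pollen-free bouts only (a bee carrying pollen
  collects marginal nectar, so such bouts are excluded outright rather than
  mass-corrected). Negative rates are retained with a QC flag — truncation
  would bias the estimator.
* **pollen rate** = mean ordinal load score (small = 1, medium = 2,
  large = 3, very large = 4) / mean bout duration, in score/min.

Durations in the denominators are means over the observed bouts themselves
(the records being averaged), not over all RFID bouts; this is exposed as a
choice rather than buried. The **experience** covariate defaults to the
bee's total completed bout count — the only experience-like quantity
recoverable from the RFID log alone; a variant counting observed same-resource
bouts is selectable.

## Model comparison

For each response the candidate set is deliberately small (bottom-up model
building, which avoids over-parameterisation at these sample sizes): a basic
model with only an intercept and a colony random intercept, plus one
single-covariate model per candidate (colony age, worker age, worker mass,
and — for the two collection rates only — experience). Mean bouts per day
and mean bout duration are square-root transformed before a Gaussian fit;
days foraged uses a Poisson GLMM with log link, fitted on foragers (zero-day
bees excluded; no zero-truncation applied). All fits are **maximum
likelihood, not REML**: AICc comparisons across different fixed-effect
structures are invalid under REML. The parameter count `k` includes variance
components, so

$$\mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n-k-1}.$$

The best candidate (lowest AICc; ties broken toward fewer parameters) is
refitted with the LPI added; LPI is declared to *predict* the response only
when this lowers the AICc by more than 2. Singular fits (colony variance at
zero) are retained — they reduce exactly to the fixed-effects model — while
outright non-convergence excludes a candidate from the table. A
derivative-free optimizer retry (bobyqa) precedes any non-convergence
verdict. Supporting descriptive statistics (Spearman rank correlation with
t-approximation p, one-way ANOVA, Mann-Whitney U with tie-corrected normal
z) round out the module.

## What the synthetic cohort emulates

`simulation_config()` defaults encode the study conditions the pipeline was
designed around; they are fixed properties of the generator, not tuning
knobs:

| quantity | default | note |
|---|---|---|
| colonies × bees | 5 × U{15, 21} | 75–105 tested workers |
| latent `y0` | 10 × Beta(1.5, 6) | errors per block, mean ≈ 2 |
| latent `A` | (10 − y0) × Beta(5, 2) | keeps `y0 + A ≤ 10` by construction |
| latent `t` | log-normal(log 20, 0.5) | choices |
| LPI effect on log days foraged | +0.06 per LPI unit | slower learners forage more days |
| colony-age effect on √(bouts/day) | −0.52 per day | older colonies: fewer bouts |
| colony-age effect on √(duration) | +0.06 per day | older colonies: longer bouts |
| non-forager fraction | 0.42 | leave once, never return |
| consecutive-day fraction | 0.92 | unbroken foraging runs |
| observed-bout fraction | 0.094 | weighing-station sampling |
| pollen-bout probability | 1/3 | of observed bouts |

Choice sequences are generated directly from the latent curve: the
per-choice error probability at aligned index `x` is
`(y0 + A e^{-x/t})/10`, and pre-probe visits are drawn at the curve's
starting probability — a bee whose starting error probability is 1 never
probes yellow and emits an all-blue, unfittable sequence, exactly the
failure mode the fitter must tolerate. Days foraged are Poisson on the log
link; bout counts and durations are laid out inside a 15-hour daily
foraging window (log-normal durations around the square-root-scale linear
predictor — strictly positive and right-skewed, like real trip durations),
with small random gaps, so event streams are physically consistent
(non-overlapping, alternating). Timestamps are seconds on a fixed UTC
origin, rendered as ISO 8601 in files. Pollen-load categories are uniform
over the four classes, there being no published distribution to emulate.
Masses come from a Gaussian body-mass model plus a Gaussian nectar crop
load and balance noise.

Features of real data the generator deliberately does **not** emulate: no
spatial foraging landscape or flower-patch structure, no weather, no reader
dropout (the cleaning rules are exercised by dedicated messy fixtures
instead), no senescence trend in bout duration. Passing tests therefore
demonstrate that the *pipeline* recovers the structure it assumes, not that
the field system is free of those complications.

The intercepts for bouts/day (√ scale 3.4 ≈ 11.6 bouts/day) and duration
(√ scale 6.5 ≈ 42 min) were chosen once so that a day's expected foraging
load fits inside the daily window across the colony-age range; bouts that
would overflow the window are dropped, which keeps event streams valid at
the cost of mild attenuation at the busy extreme.

## Numerical choices and degenerate inputs

* Derived square-root-scale means below 0.5 are clipped there with a
  warning rather than allowed to go negative.
* Bout extraction tie-breaks: at an identical second, an "out" read sorts
  before an "in" read; the resulting zero-length candidate is removed by the
  duration floor.
* Empty inputs (no events, no bouts, no observations) propagate as empty
  tables, never errors.
* A constant response makes the Gaussian likelihood unbounded; such a
  candidate is reported non-convergent and excluded from its table.
* One-way ANOVA on identical constant groups returns F = 0 rather than 0/0.

## Problem sizes used by the test suite

The suite fits one full synthetic study (85-ish bees) per replicate and
uses 100 replicates for the selection-recovery property, 200 bees for
parameter recovery, 1000 random streams (≤ 50 reads) for the bout-pairing
oracle, and a 5 × 175-bee cohort for coefficient coverage at n ≈ 500 —
sizes chosen to make sampling error small relative to the asserted margins
while keeping a full run in minutes on one core.

## Known limitations

* The decay constant `t` is intrinsically poorly determined from a single
  100-choice sequence: a Cramér–Rao calculation on the per-choice binomial
  model puts the attainable relative standard error near or above 50% for
  realistic parameters. The LPI — which integrates the whole curve — is far
  more stable, which is one good reason to prefer it as the primary
  learning measure.
* With only five colonies, colony-level covariates (colony age) compete
  directly with the colony random intercept; their estimates rest on five
  effective observations and should be read accordingly.
* The experience covariate is a reconstruction (total completed bouts); the
  original covariate definition is not recoverable from the event log alone.
* The Poisson days-foraged model applies no overdispersion correction and
  no offset; none is applied here either.
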