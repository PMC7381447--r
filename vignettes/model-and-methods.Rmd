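---
title: "Models, fitting machinery, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, fitting machinery, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(searchddm)
```

## The scientific question

When people hold two colors in visual working memory (VWM) and then search
a display in which the target and/or a distractor can carry one of those
colors, search is faster on target-match trials and slower on
distractor-match trials. Two accounts of this guidance differ at the level
of individual trials:

* **MIT (Multiple-Item-Template)** — both memory items act as attentional
  templates concurrently: facilitation on *every* target-match trial,
  interference on *every* distractor-match trial, and approximate
  cancellation when both match.
* **SIT (Single-Item-Template)** — only one memory item is the active
  template on a given trial, so facilitation or interference each occur on
  a random 50% of match trials, and both-match trials are a 50/50 mixture
  of fast (target-guided) and slow (distractor-guided) trials.

Mean RTs barely distinguish the accounts; trial-level RT *distributions*
do. Under MIT, both-match and non-match trials share one distribution;
under SIT the both-match distribution is a bimodal mixture and hence wider.
`searchddm` implements the full simulation-and-fitting pipeline that turns
this distributional prediction into a model comparison.

## The accumulator

Responses are generated by a discrete-time, two-boundary accumulator. The
activation starts at 0; each 1-ms sample adds a drift rate $v$ plus
Gaussian noise of standard deviation $s$. Absorption at $+1$ (the fixed
threshold) produces a correct response with RT equal to the sample index;
absorption at $-1$ an error. An attempt that has not been absorbed after
2000 samples (the response deadline) is discarded and restarted; 1000
fruitless attempts are a *simulation failure*. There is no non-decision
time, starting-point bias, or across-trial drift variability: the model is
deliberately minimal, and fidelity to that minimal form is preferred over
realism throughout.

Two continuum-limit oracles back the test suite: the absorption
probability $1/(1+e^{-2 v A/s^2})$ and the mean decision time
$(A/v)\tanh(vA/s^2)$. These are exact for the Wiener process, not for the
discrete walk: each Gaussian step overshoots the boundary by
$\approx 0.58\,s$ on average, which inflates the effective threshold.
At $s = 0.05$ the walk is measurably slower (by about 3%) and more
accurate (by about 0.2 points of percent) than the continuum formulas —
visible at Monte-Carlo resolution well below $n = 10^5$. Oracle-agreement
tests therefore run in a small-step regime ($s \le 0.01$), and a separate
test documents the size and sign of the coarse-step bias. This is a
property of any faithful 1-ms-step implementation, not an implementation
artifact.

## Drift-rate schedules

The template models add a single *drift-rate change* parameter
$\Delta \ge 0$, applied per trial according to the hypothesis:

| Trial type | MIT | SIT |
|---|---|---|
| Non-match | $v$ | $v$ |
| Target match | $v+\Delta$ | $v+\Delta$ or $v$, 50/50 |
| Distractor match | $v-\Delta$ | $v-\Delta$ or $v$, 50/50 |
| Both match | $v$ | $v+\Delta$ or $v-\Delta$, 50/50 |

SIT's template assignment is drawn independently per trial; one draw
decides the whole trial. $v-\Delta$ may be negative (only the base drift
is constrained positive). A single $\Delta$ serves both facilitation and
interference.

A caution established during development: the intuition "the SIT
both-match mixture is wider than non-match" holds for the *mixture gap*
but competes with the fact that the facilitated component is *narrower*
than the base distribution. At noise 0.03 with the deadline truncating the
slow tail, the variances nearly cancel; the widening is unambiguous at
noise near 0.02. Distribution-level tests run there.

## The synthetic cohort

The generator reproduces the experiments' structure: 2 (target match) x 2
(distractor match) x 2 (orientation congruency) factor cells, exactly
balanced within every 32-trial block, 8 test blocks (256 test trials) plus
one flagged practice block; two memory hues per trial drawn uniformly on
the color circle with rejection until they are at least 30 degrees apart.
Congruency does not enter the diffusion model; an optional additive
congruency drift offset (default 0) exists only so the descriptive stage
has something to describe.

Participant-level parameters are log-normal around
$v = 0.0011$, $s = 0.03$ (coefficient of variation 0.2), giving mean
correct RTs near 750 ms and accuracies near 0.9 — the broad regime of the
human cohorts. The default drift-rate change is $\Delta = 8\times10^{-4}$,
calibrated once so that the MIT-generated cohort's model-comparison effect
size matches the published comparison (paired $d \approx 0.6$). The
implied condition effects (roughly $\pm$250–300 ms) are larger than
typical human capture effects: an observer with no non-decision time and
no lapses needs a stronger drift contrast to produce the same
discriminability as human data. Cohorts are a pure function of the master
seed (participant $i$ uses child seed `master_seed + i`).

What the generator does *not* emulate: non-decision time, lapses,
fatigue/practice trends, the color-wheel memory test (only the hue pair is
kept), and display rendering. Consequently, passing tests on synthetic
cohorts show that the *machinery* behaves as specified — they do not show
that human data satisfies the models' assumptions.

## Preprocessing

Fixed order, matching the reported rules: drop the practice block; drop
trials with RT strictly below 200 ms or strictly above 2000 ms (boundary
values are kept); then drop participants whose accuracy on the remaining
trials is below 0.7 (the denominator choice — RT-filtered test trials — is
configurable, since the original rule does not state it). Only correct-
trial RTs enter the distributional analyses. Condition summaries report
within-subject 95% confidence intervals via the Cousineau–Morey
normalization (subject-centering plus the $\sqrt{C/(C-1)}$ correction).

## The two-stage rank-ordered RSS fit

**Stage 1** estimates $(v, s)$ per participant: observed RTs are ordered
by correctness (errors first) and then value; the simulator generates a
response vector with *exactly matched* correct/incorrect counts; both
vectors are compared by the residual sum of squares (RSS). Matching counts
by conditional simulation has a consequence worth stating plainly: because
the symmetric accumulator's correct and error RT distributions are
identical at a given drift, the matched-count objective carries *no
error-rate information* — $(v, s)$ are identified by distribution shape
alone. At high accuracy the shape alone is nearly ridge-degenerate between
strong-drift and noise-dominated solutions; the estimator is reliable in
moderate-accuracy regimes (roughly 0.85–0.95).

**Stage 2** holds $(v, s)$ fixed and estimates $\Delta$ for each template
model, with the nested ordering correctness -> trial type (non, target,
distractor, both) -> value, and per-cell matched simulation under the
model's schedule. For SIT, each simulated response draws its template
*before* conditioning and keeps it while the walk is re-run: a required
error under a strongly facilitatory template can then be unreachable
within the 1000-attempt cap. That — and only that — reading produces the
reported asymmetric failure mode ("failed to generate a sufficient number
of incorrect responses") that disqualifies SIT for some participants while
MIT always fits.

### Optimizer machinery

The objective is stochastic, so the implementation invests in variance
control:

* **Counter-based common random numbers.** Every simulation attempt runs
  on its own splitmix64 substream keyed by (call seed, trial, attempt);
  call seeds are drawn from R's RNG, so `set.seed()` still determines
  everything. Re-evaluating the objective at a nearby candidate replays
  the same Gaussian increments, making the RSS profile smooth in the
  parameters.
* **Pool-filling conditional simulation.** Cells that share one drift are
  filled from a single unconditional stream (first $n$ outcomes of a
  category are i.i.d. draws from the category-conditional law), at about
  half the cost of per-response rejection, with the same failure
  semantics (an attempt-cap of consecutive misses).
* **Stratified template splits.** Mixture cells assign each template to
  half the responses (odd one randomized) rather than i.i.d. per
  response. The i.i.d. split adds binomial assignment variance to every
  SIT evaluation, which systematically inflates SIT's minimized RSS and
  biases the model comparison toward MIT on *any* data; stratification
  estimates the same 50/50 mixture with less variance. The i.i.d. variant
  remains available (`template_split = "iid"`).
* **Replicate averaging and quadratic refinement.** Objectives can
  average `n_rep` seeded replicates; stage 1 uses a log-spaced grid plus
  Nelder–Mead, stage 2 a coarse-plus-fine grid with a quadratic-vertex
  estimate of the minimum. Grid bounds: $v \in [10^{-4}, 10^{-1}]$,
  $s \in [10^{-3}, 0.5]$, $\Delta \in [0, 2\hat v]$. Candidates whose
  continuum mean decision time exceeds the deadline are rejected without
  simulation. The two models' stage-2 fits share one seed, so their
  paired RSS difference largely cancels simulation noise.

### What recovery studies showed

Parameter recovery at 256 trials is information-limited. A small $\Delta$
(a few $10^{-4}$) cannot be recovered to better than ~40–60% median
relative error by this procedure regardless of optimizer effort — the
incorrect-response block of the rank-ordered vector is few trials with
enormous variance and dominates the stage-2 objective. The package's
recovery validation therefore runs at a strong-interference reference
point ($v = 0.0011$, $s = 0.032$, $\Delta = 10^{-3}$), chosen once from an
identifiability calibration and then frozen; there the two-stage fit
recovers $v$ and $s$ to ~15–20% and $\Delta$ to ~20–25% median relative
error.

Model recovery is *asymmetric*. MIT-generated cohorts are attributed to
MIT. SIT-generated cohorts frequently are not: stage 1 fits a single-drift
accumulator to pooled bimodal data, absorbing the mixture width into
$\hat s$; MIT with a moderate $\Delta$ then mimics the widened data, while
SIT — simulating mixtures on top of the inflated $\hat s$ — overshoots.
This is a substantive caveat to the two-stage RSS comparison itself: on
data for which SIT is true, the procedure's verdict for MIT cannot be
taken at face value. The package reports it as measured rather than
papering over it. Relatedly, the failure-to-fit diagnostic can never
trigger on data generated by the fitted model itself (the fitted error
rates are always commensurate with the data's); it requires the kind of
misspecification human data carries. The test fixture reproduces it by
adding a constant 350-ms non-decision shift and a few lapse errors to
low-error synthetic participants, which drives $\hat v/\hat s^2$ into the
regime where SIT's non-matching template cannot produce a required error.

## Distribution-width analysis

Correct RTs per participant and condition are fitted by maximum likelihood
with the three-parameter inverse-Gaussian family (shape, location, scale —
the scale being the stretch of the location-scale family), multi-started
from Wald moment estimates with the location bounded below the sample
minimum; cells smaller than 10 trials are refused, not fabricated. The
paired both-match vs non-match comparison reports the classical t and the
JZS Bayes factor as BF01 (evidence for equal widths). Note that on
strongly bimodal data the shape parameter absorbs part of the width, so
the scale alone is not monotone in spread; the fitted implied SD
(scale $\times$ shape$^{3/2}$) is reported alongside as the
parameterization-free width summary. A closed-form two-parameter Wald fit
cross-checks the numerical optimum.

## Bayesian machinery

The default Bayes factor for the paired t-test places a Cauchy prior of
scale $r = \sqrt{2}/2$ on the standardized effect and integrates the
resulting inverse-gamma mixture over $g$ by adaptive quadrature; the
quadrature's own relative error bound is reported. At the published worked
example ($t = 4.20$, $n = 44$) it yields BF10 $\approx 184.5$. Evidence
labels follow the conventional ladder (anecdotal / moderate / strong /
very strong between 1–3, 3–10, 10–30, 30–100 and reciprocals), extended
with "extreme" beyond 100.

## Numerical and degenerate-input policy

Zero-variance difference vectors are analysis errors in `paired_t()` but
produce $t = 0$ in the two comparison reports (the substantively right
answer for identical fits). Empty cells are flagged, never imputed.
Boundary RTs (200, 2000 ms) are kept. Threshold crossing uses $\ge$ /
$\le$, so overshoot counts as crossing. All tolerances in the test suite
are engineering tolerances calibrated once against the oracles and frozen.

## Problem sizes

The validation studies use the sizes a desk replication affords: recovery
over 20 seeded replicates of single 256-trial participants; model
recovery over 20 seeded cohorts of 30 participants per generating model;
oracle agreement at $10^5$ trials. The pipeline itself is size-agnostic.

## Known limitations

* Stage 1 discards error-rate information by construction (matched-count
  conditioning); fits in very-high-accuracy regimes sit on a shape ridge.
* The model comparison is biased toward MIT on SIT-generated data (see
  above); symmetric model recovery should not be assumed.
* Small drift-rate changes are not recoverable at 256 trials.
* The continuum oracles are only valid for noise well below threshold;
  the 1-ms discretization carries an irreducible overshoot bias.
* The generator omits non-decision time and lapses, so absolute RT shapes
  differ from human data in known ways.
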