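---
title: "Decomposing overt attention in the bubble paradigm: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing overt attention in the bubble paradigm: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bubblegaze)
```

## The scientific problem

Where people look is shaped by at least three forces: low-level image
features (contrast attracts gaze), the task-dependent information content of
image regions (informative regions attract gaze), and spatial viewing biases
(the central fixation bias and the preference for short saccades). The
bubble paradigm makes these forces separable: stimuli are small, isolated,
Gaussian-masked image patches ("bubbles") shown in varying combinations
while participants classify the stimulus (facial expression or gender for
face material; scenic openness or human influence for forest material).
Because each bubble is a discrete perceptual unit, a single scalar of each
kind can be attached to every bubble, and their contributions to gaze can be
compared in one regression.

`bubblegaze` implements the four per-bubble measures and the analyses that
connect them, together with a fully synthetic experiment generator so that
every stage can be exercised, and its estimators validated, against known
ground truth without any human data.

## The four measures

### Empirical salience

The empirical salience $E_A$ of bubble $A$ is a context-independent measure
of how strongly it attracts fixations. Its defining assumption is that the
ratio of fixations landing on two bubbles shown together does not depend on
which other bubbles are present: $F_S(A)/F_S(B) = E_A/E_B$ for any stimulus
$S$ containing $A$ and $B$. Every observed mean fixation fraction
$\bar f_S(A)$ then yields one linear equation

$$E_A - \bar f_S(A) \sum_{B \in S} E_B = 0,$$

and the whole experiment yields an overdetermined linear system. We solve it
by weighted least squares (each equation weighted by the number of trials
behind its fraction) under the scale constraint $\sum E = 1$, which is
eliminated by substitution so that consistent systems are solved exactly.
Negative components — possible in principle under noise — are clipped to a
floor of $10^{-6}$ (the downstream log transform requires positivity) and
the solution renormalized; this is rare and logged. The solver's
faithfulness is summarized by the reconstruction accuracy,
$100(1 - \text{mean}\,|\hat f - \bar f|)$, over all (stimulus, bubble)
cells; on synthetic data at design scale this is around 95%.

### Stimulus-dependent (feature) salience

Luminance contrast at a pixel is the Gaussian-weighted standard deviation of
luminance in the surrounding patch, with the window equal to the bubble
construction window (sd 1.0 deg); texture contrast is the same operation
applied to an inner luminance-contrast map computed with a window a quarter
of that size (sd 0.25 deg). We read "a quarter of the size of a bubble" as a
quarter of the construction window's sd, since that window is what defines a
bubble's extent; the alternative reading (a quarter of the 6-deg patch) is
available through the `sigma_inner_deg` argument. Both contrasts are
normalized by task-wide means — not per image — so that values are
comparable across bubbles originating from different photographs.

Contrast is converted to fixation probability by a Bayes mapping calibrated
on free-viewing baseline data: contrast values are divided into 20
equal-population bins (so the feature prior is constant by construction),
and the conditional fixation probability per bin is the bias-corrected
share of baseline fixations in that bin. The spatial-bias correction
weights each fixation inversely by the central-bias density at its
location; we cap these importance weights at their 99th percentile because
the inverse density is numerically explosive in the far periphery where the
bias density is nearly zero. A bubble's feature salience is the product of
its luminance- and texture-contrast fixation probabilities (independence
assumption), so log salience is additive in the two log probabilities.

### Spatial-bias salience

A first-order generative scanpath model captures where people would look
given only bubble positions and oculomotor regularities. From baseline
trials we estimate a central-bias map (fixation locations) and a saccade
map (displacement vectors), each as an equal-weight average of per-trial
histograms smoothed with a 0.5-deg Gaussian and normalized to unit mass.
For each simulated trial the sampling density of the next fixation is the
point-wise product of (i) the central-bias map, (ii) the stimulus's bubble
position map — the point-wise maximum of the per-bubble Gaussian envelopes,
which avoids double-counting where tails overlap — and (iii) the saccade
map centered on the current fixation (the screen center before the first
fixation), renormalized each step. The model has no inhibition of return;
it is Markovian by construction. Trajectories are simulated with per-trial
fixation counts matched to the corresponding experimental trial, and the
simulated fixations are pushed through exactly the same fraction/solver
pipeline as real ones, yielding a spatial-bias salience on the same global
scale.

The simulation grid is 3 cells per degree by default (a parameter). At the
display's native 33 px/deg the per-step product-and-sample update would be
two orders of magnitude more expensive while the maps involved are smooth
at the 0.5-deg smoothing scale, so the coarser grid changes nothing
statistically; sub-cell positions are drawn uniformly within a cell.

### Bubble information

Each bubble carries a latent response distribution $P_R(B)$ over the task's
classes; its information is $I(B) = E_{max} - E(P_R(B))$ bits, with
$E_{max} = \log_2 C$ (2 bit for the four-class expression task, 1 bit
elsewhere). Responses to a multi-bubble stimulus are modeled as draws from
the p-model integration

$$Z(P_1, \dots, P_n)[c] \propto \prod_i P_i[c],$$

the normalized component-wise product — the Bayes-optimal fusion of
independent evidence. $Z$ is commutative and associative, the flat
distribution is its identity, and zeros are absorbing per class.

All bubble distributions of a task are estimated jointly by maximum
likelihood: bubble $B$ is parameterized by $C-1$ unconstrained reals through
a softmax, giving $n_{bubbles} \times (C-1)$ free parameters (282 for 94
four-class bubbles), and the likelihood of all observed responses under the
p-model is maximized by BFGS with an analytic gradient, five seeded random
restarts by default, and a relative convergence tolerance of $10^{-8}$.
Probabilities are floored at $10^{-6}$ inside the likelihood so boundary
deltas cannot produce infinite terms. The number of scalar equations is
reported under both bookkeeping conventions ($C$ or $C-1$ components per
stimulus), since either convention is defensible and nothing downstream
depends on the choice.

### Relating the measures

All three predictors and the outcome are log-transformed (natural log;
correlations are base-invariant) with a floor of $10^{-6}$ for saliences
and 0.01 bit for information — information values pile up near zero, and
without the larger floor its log would span many orders of magnitude driven
by numerically tiny entropies. Per task we report pairwise Pearson
correlations with two-sided t-tests, the multivariate OLS fit (with
intercept) with its $R^2$ and overall F-test, and semi-partial correlations:
predictor $j$ is regressed on the other predictors and the residual is
correlated with the outcome, so $sr_j^2$ is exactly the unique contribution
$R^2_{full} - R^2_{without\,j}$ (an identity the tests verify to machine
precision). Significance of $sr_j$ uses the t-test on the residual
correlation; the analyses are always run per task, never pooled.

## The synthetic world

The generator's defaults emulate the study design: 75 participants, 280
trials each (70 per task), about 6.2 analyzed fixations per trial, four
tasks with 94/94/88/89 bubbles drawn from 24/24/36/36 source images, 500
stimuli per task composed of 1–5 bubbles (12/42/26/14/2% of non-full-field
stimuli) in the conditions same/congruent/incongruent/permuted/full-field
(50/15/15/16/4%), non-overlapping bubble placements (centers at least 4 deg
apart — the envelopes then share under 5% of their mass), and a 27-
participant free-viewing baseline. Stimulus assembly balances bubble usage
with a least-used-first heuristic.

Ground truth per bubble consists of: a response distribution drawn from a
symmetric Dirichlet (concentration 0.5, so information spans its full
range), relabeled so the dominant class matches the bubble's source class; a
log-normal feature component realized as a contrast bump in the synthetic
images at the bubble's position; and a spatial component given by a
Gaussian central-bias profile (sd 5 deg) at the bubble's position. True
empirical salience is $\exp(w \cdot z(\log \text{components}) + \epsilon)$
with weights $(0.20, 0.35, 0.50)$ for (feature, information, spatial) and
log-noise sd 0.3 — the spatial bias strongest, information close behind,
features weakest, mirroring the qualitative ordering reported for human
data. The log-components are standardized before weighting so that the
weights are comparable effect sizes; semi-partial correlations are
scale-free, so this choice is what makes "the sr ordering matches the
weight ordering" a well-posed recovery target.

Fixations target bubbles with probability proportional to true salience;
landing points scatter isotropically (sd 0.45 deg, giving a first-fixation
median distance near 1.05 deg), and consecutive fixations on the same
bubble are drawn from a tighter scatter whose Rayleigh mean is 0.16 deg
smaller — corrective saccades are modeled as an independent re-landing
rather than a sequential shrink, which leaves the paired first-minus-
subsequent expectation identical and keeps the generator vectorized. The
per-trial fixation count is truncated Poisson (at least 1) with mean 6.2;
only the mean is constrained by the emulated design, the distributional
form is a generator choice. Responses are drawn from the p-model
integration of the stimulus's true distributions; full-field stimuli use a
class-dominant distribution with 94% mass on the true class.

Synthetic images are band-limited Gaussian noise whose local sd follows a
prescribed contrast field (base 0.04 plus bumps of up to 0.20 at bubble
centers, scaled by the planted feature component). The noise bandlimit is
0.125 deg: with a coarser bandlimit the 1-deg analysis window averages too
few independent noise cells and the measured contrast at a bubble center
becomes a noisy readout of the planted field. Images are rendered at 8
px/deg; the contrast measures are resolution-invariant at this scale.

What the generator does *not* emulate: photorealistic structure (faces,
scenes), correlations between feature content and information content
beyond those induced by position, response times, fatigue or learning
effects, eye-tracker noise, and calibration drift. Passing tests therefore
demonstrate that the estimators recover what they are defined to recover
under the paradigm's assumptions — not that those assumptions hold for any
particular human dataset.

## Numerical choices and degenerate inputs

* Nearest-bubble assignment uses a 3.0-deg radius; ties break to the
  lexicographically smallest bubble id. Fixations within 1.5 deg of the
  screen center (a choice; no radius is canonical) count as "center",
  everything else as scattered. The excluded first fixation of each trial
  is flagged with index 0.
* The eccentricity-dependent filter in bubble rendering is a Gaussian blur
  whose sd grows linearly at 0.1 deg of blur per degree of eccentricity
  (configurable); only the blur-with-eccentricity contract matters for the
  paradigm (scanning a bubble must not reveal more than fixating its
  center).
* Equal-population bin edges sit at midpoints between adjacent order
  statistics; massive ties collapse duplicate edges and flag the binning.
  Empty fixation bins are floored at $10^{-6}$.
* `solve_salience` handles disconnected bubbles (never fixated anywhere) by
  assigning the floor and flagging them rather than failing.
* In `permutation_position_test` the statistic (max absolute difference of
  class proportions) is nonnegative, so the "central 95% region" is
  implemented as $[0, q_{0.95}]$ of the Monte-Carlo null — identical
  response pairs (statistic 0) are always inside.
* The information-error "lower bound" resamples responses from the fitted
  distributions at the real per-stimulus trial counts. Because the ML fit
  tracks the observed responses, the *in-sample* error can fall below this
  bound at high response density; the bound-ordering property is therefore
  validated out-of-sample (fit on one replicate, error on an independent
  one).

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: hand
computations and closed forms (the Rayleigh median
$\sigma\sqrt{2\ln 2} = 1.18$ deg at $\sigma = 1$; the p-model on printed
cases; the added-last identity $sr_j^2 = R^2_{full} - R^2_{-j}$),
brute-force reimplementations (sliding-window contrast, normalized-product
integration, exhaustive mask summation for the trajectory model under flat
biases), and known-generator recovery (planted saliences, planted contrast
fields, planted central bias, planted mixture weights). Stochastic checks
run at the sizes that keep the full suite within a few minutes: the
information-fit recovery uses 20 seeded replicates of the four-class task
at the design's full trial budget of 21000 responses (where the estimator's
mean absolute error is about 0.09 bit and its bias about 0.03 bit — at the
per-task split of 5250 responses the 282-parameter fit is visibly
overfit-biased and that regime is reported, not hidden); weight-recovery
uses 10 replicates at the per-task trial budget; calibration checks use
250–500 Monte-Carlo replicates.

## Known limitations

* The empirical-salience model assumes context independence; real gaze data
  can violate it (e.g., configural processing of faces), and the solver
  will average over such violations rather than detect them.
* The feature mapping's equal-population bins quantize extreme contrast
  values; bubbles far outside the calibrated contrast range share the
  terminal bins.
* The max-model integration is implemented as an alternative but no model
  comparison machinery beyond log-likelihood is provided; integration
  variants that weight contradictory evidence are out of scope.
* The trajectory model is strictly first-order (no inhibition of return, no
  duration model), and the spatial-bias salience inherits any estimation
  error of the baseline bias maps.
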