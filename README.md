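# bubblegaze

Quantifying what drives overt visual attention — low-level image features,
task-dependent information content, and spatial viewing biases — in
bubble-paradigm eye-tracking experiments.

## The problem

In the bubble paradigm, observers classify stimuli composed of 1–5 small,
Gaussian-masked image patches ("bubbles") while their eye movements are
recorded. Because each bubble is a discrete perceptual unit, four scalar
measures can be attached to every bubble:

* **Empirical salience** `E_A`: how strongly a bubble attracts fixations,
  independent of stimulus context. Defined by `F_S(A)/F_S(B) = E_A/E_B` for
  any stimulus `S`; estimated as the constrained weighted least-squares
  solution of the stacked equations
  `E_A − f̄_S(A) · Σ_{B∈S} E_B = 0` under `Σ E = 1`.
* **Stimulus-dependent salience**: the product of fixation probabilities
  conditioned on luminance contrast `LC(x)` (Gaussian-windowed local sd of
  luminance over task mean luminance) and texture contrast `TC(x)` (the
  same operation on an inner `LC` map), calibrated on free-viewing baseline
  data via a Bayes mapping over 20 equal-population bins with inverse
  central-bias weighting.
* **Spatial-bias salience**: fixation propensity predicted by a generative
  scanpath model — central-bias map × bubble-position map × saccade map
  shifted to the current fixation, renormalized each step — then passed
  through the same global salience solver.
* **Bubble information** `I(B) = log2(C) − H(P_R(B))` bits: how much a
  bubble alone resolves the classification task. Per-bubble response
  distributions are estimated by a global maximum-likelihood fit under the
  p-model `Z(P_1,…,P_n)[c] ∝ Π_i P_i[c]`, the normalized product
  integration of independent evidence (`n_bubbles × (C−1)` free
  parameters, e.g. 282 for 94 four-class bubbles).

A per-task regression of log empirical salience on the three log-predictors
— pairwise, multivariate, and semi-partial correlations — quantifies each
factor's total and unique contribution.

The package also ships a seeded synthetic-experiment generator (stimulus
sets with the paradigm's composition, fixation trajectories with central
bias and corrective saccades, p-model classification responses, free-viewing
baseline) so the entire pipeline is testable against known ground truth.

## Worked example

```r
library(bubblegaze)

geom <- screen_geometry()                      # 1024x786 px at 33 px/deg
pool <- sample_bubble_pool("gender", n_bubbles = 94, n_images = 24,
                           geometry = geom, seed = 2)
stimset <- build_stimulus_set(pool, n_stimuli = 500, seed = 3)
truth <- sample_ground_truth(pool, seed = 4)

design <- experiment_design(trials_per_participant = 70, tasks = "gender")
expt <- generate_experiment(stimset, truth, design, geom, seed = 5)

fr <- observed_fractions(expt$trials, stimset, geom)
emp <- solve_salience(fr, stimset)
reconstruction_accuracy(emp, fr, stimset)
#> [1] 95.31638

fit <- fit_bubble_distributions(expt$responses, stimset,
                                task_classes("gender"), seed = 6)
fit
#> <bubble_fit> 94 bubbles, 2 classes: 94 free parameters, 480 stimuli
#>   log-likelihood -818.54 (converged)
#>   bubble information: median 0.506 bit, range [0.000, 1.000]
```

The reconstruction accuracy (95.3%) says that the context-independent
saliences reproduce the observed per-stimulus fixation splits to within
~0.05 on average — the empirical-salience model is a faithful summary. The
fit reports one response distribution per bubble; its per-bubble
information feeds the final regression, run for all three predictors by
`attention_analysis()` or for a whole multi-task study by
`run_bubble_study()`.

## Package layout

* `R/stimuli.R`, `R/fixations.R` — bubble geometry, stimulus assembly,
  fixation assignment and distance statistics
* `R/synthetic.R` — the synthetic world: pools, ground truth, images,
  experiments, baseline
* `R/empirical.R`, `R/features.R`, `R/spatial.R`, `R/information.R` — the
  four per-bubble measures
* `R/regression.R` — correlation / semi-partial / multivariate analyses
* `R/pipeline.R`, `R/io.R` — end-to-end study driver and table formats
* `vignettes/bubblegaze-methods.Rmd` — models, assumptions, parameter
  choices, and validation strategy
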