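#' Run a complete synthetic bubble study end to end
#'
#' Generates a full synthetic experiment from one seed and runs every
#' analysis stage on it: bubble pools and ground truth, stimulus sets,
#' trials with fixations and responses, the free-viewing baseline, the
#' empirical-salience solve with its reconstruction accuracy, the
#' feature-salience calibration, the spatial-bias simulation and salience,
#' the global information fit with its prediction error and sampling lower
#' bound, and the final correlation decomposition per task.
#'
#' @param design An [experiment_design()]; the defaults reproduce the
#'   emulated study's scale (75 participants, 280 trials each).
#' @param geometry A [screen_geometry()].
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @param bias_res Grid resolution (cells per degree) for bias maps and
#'   trajectory simulation.
#' @param img_px_per_deg Resolution of the synthetic images.
#' @param baseline_trials_each Baseline trials per baseline participant.
#' @param verbose Print stage progress.
#' @return List with per-task results (`truth`, `stimset`, `empirical`,
#'   `feature`, `spatial`, `fit`, `analysis`, ...) plus study-level tables.
#' @export
run_bubble_study <- function(design = experiment_design(),
                             geometry = screen_geometry(), seed = 1,
                             bias_res = 3, img_px_per_deg = 8,
                             baseline_trials_each = 60, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seed_of <- function(k) (seed * 97L + k) %% .Machine$integer.max

  tasks <- design$tasks
  pools <- truths <- stimsets <- list()
  for (ti in seq_along(tasks)) {
    task <- tasks[ti]
    pools[[task]] <- sample_bubble_pool(task, design$n_bubbles[[task]],
                                        design$n_images[[task]], geometry,
                                        seed = seed_of(ti))
    truths[[task]] <- sample_ground_truth(pools[[task]], geometry = geometry,
                                          seed = seed_of(10 + ti))
    stimsets[[task]] <- build_stimulus_set(pools[[task]],
                                           design$n_stimuli_per_task,
                                           design$condition_props,
                                           design$count_props,
                                           seed = seed_of(20 + ti))
  }

  say("generating experiment (%d participants x %d trials)",
      design$n_participants, design$trials_per_participant)
  expt <- generate_experiment(stimsets, truths, design, geometry,
                              seed = seed_of(30))

  say("generating free-viewing baseline")
  baseline <- generate_baseline(geometry, trials_each = baseline_trials_each,
                                seed = seed_of(31))
  maps <- estimate_bias_maps(baseline, geometry, res = bias_res)

  results <- list(design = design, geometry = geometry, seed = seed,
                  bias_maps = maps, expt = expt, tasks = list())
  for (task in tasks) {
    say("analyzing task %s", task)
    ss <- stimsets[[task]]
    tr <- truths[[task]]
    trials <- expt$trials[expt$trials$task == task, , drop = FALSE]
    responses <- expt$responses[expt$responses$task == task, , drop = FALSE]

    ## empirical salience
    fr <- observed_fractions(trials, ss, geometry)
    emp <- solve_salience(fr, ss)
    acc <- reconstruction_accuracy(emp, fr, ss)

    ## feature salience: planted-contrast images + baseline calibration
    fields <- planted_contrast_fields(pools[[task]], tr, geometry,
                                      img_px_per_deg)
    images <- generate_images(fields, px_per_deg = img_px_per_deg,
                              seed = seed_of(40))
    fmaps <- contrast_maps(images, img_px_per_deg)
    avail_lc <- unlist(fmaps$LC)
    avail_tc <- unlist(fmaps$TC)
    bins_lc <- equal_population_bins(avail_lc)
    bins_tc <- equal_population_bins(avail_tc)
    fbase <- generate_baseline(geometry, n_participants = 27,
                               trials_each = 60, mean_fixations = 10,
                               images = images, feature_maps = fmaps,
                               feature_fun = function(v) v,
                               seed = seed_of(41))
    ## inverse-bias importance weights, capped to keep their variance sane
    w <- 1 / pmax(bias_density_at(maps, fbase$x_deg, fbase$y_deg), 1e-9)
    w <- pmin(w, stats::quantile(w, 0.99))
    lc_fix <- mapply(function(im, x, y) feature_value_at(fmaps, im, x, y, "LC"),
                     fbase$image, fbase$x_deg, fbase$y_deg)
    tc_fix <- mapply(function(im, x, y) feature_value_at(fmaps, im, x, y, "TC"),
                     fbase$image, fbase$x_deg, fbase$y_deg)
    map_lc <- feature_fixation_mapping(lc_fix, bins_lc, w)
    map_tc <- feature_fixation_mapping(tc_fix, bins_tc, w)
    feat <- stimulus_dependent_salience(pools[[task]], fmaps, map_lc, map_tc)

    ## spatial-bias salience from simulated trajectories
    lens <- stats::aggregate(fix_index ~ participant + stimulus,
                             data = trials[trials$fix_index > 0, ],
                             FUN = length)
    names(lens)[3] <- "n_fix"
    sim <- simulate_trajectories(ss, maps, lens, seed = seed_of(50))
    spa <- spatial_bias_salience(sim, ss, geometry)

    ## bubble information from the global fit
    fit <- fit_bubble_distributions(responses, ss, tr$classes,
                                    seed = seed_of(60))
    perr <- info_prediction_error(fit, responses, ss, reps = 50,
                                  seed = seed_of(61))

    ana <- attention_analysis(emp, feat, fit$information, spa)
    results$tasks[[task]] <- list(
      pool = pools[[task]], truth = tr, stimset = ss,
      fractions = fr, empirical = emp, reconstruction_accuracy = acc,
      feature = feat, spatial = spa, fit = fit,
      info_error = perr, analysis = ana
    )
  }
  results
}
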