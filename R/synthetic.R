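#' Design parameters of a synthetic bubble experiment
#'
#' Bundles the study-level constants of the emulated experiment: 75
#' participants with 280 trials each (70 per task over four tasks, 21000
#' trials in total), a mean of 6.2 fixations per trial (truncated Poisson),
#' the condition and bubble-count composition of the stimulus set, the
#' landing scatter of fixations around bubble centers, and the corrective-
#' saccade approach (subsequent fixations on a bubble land on average
#' 0.16 degrees closer to its center than first fixations).
#'
#' @param n_participants Number of participants.
#' @param trials_per_participant Trials per participant (split evenly over
#'   the tasks).
#' @param tasks Character vector of tasks.
#' @param mean_fixations Mean number of analyzed fixations per trial.
#' @param landing_sd_deg Isotropic scatter (per-axis sd) of first fixations
#'   around the targeted bubble center.
#' @param approach_deg Mean radial approach of subsequent fixations.
#' @param fullfield_accuracy Probability mass on the true class for
#'   responses to full-field stimuli.
#' @param condition_props,count_props Stimulus composition, see
#'   [build_stimulus_set()].
#' @param n_stimuli_per_task Stimuli assembled per task.
#' @param n_bubbles Named vector: bubble pool size per task.
#' @param n_images Named vector: source images per task.
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(n_participants = 75,
                              trials_per_participant = 280,
                              tasks = c("expression", "gender", "influence", "space"),
                              mean_fixations = 6.2,
                              landing_sd_deg = 0.45,
                              approach_deg = 0.16,
                              fullfield_accuracy = 0.94,
                              condition_props = c(same = 0.50, congruent = 0.15,
                                                  incongruent = 0.15,
                                                  permuted = 0.16, fullfield = 0.04),
                              count_props = c(`1` = 0.12, `2` = 0.42, `3` = 0.26,
                                              `4` = 0.14, `5` = 0.02),
                              n_stimuli_per_task = 500,
                              n_bubbles = c(expression = 94, gender = 94,
                                            influence = 88, space = 89),
                              n_images = c(expression = 24, gender = 24,
                                           influence = 36, space = 36)) {
  stopifnot(n_participants > 0, trials_per_participant > 0,
            trials_per_participant %% length(tasks) == 0,
            abs(sum(condition_props) - 1) < 1e-9,
            abs(sum(count_props) + condition_props[["fullfield"]] - 1) < 1e-9)
  out <- as.list(environment())
  class(out) <- "experiment_design"
  out
}

#' Sample a bubble pool for one task
#'
#' Lays out candidate bubble positions on a grid with at least
#' `min_sep_deg` separation (so any combination of distinct positions obeys
#' the non-overlap constraint), assigns source images to balanced classes,
#' and distributes the requested number of bubbles over images and
#' positions. Positions are shared between images, which makes congruent /
#' incongruent / permuted combinations possible.
#'
#' @param task Task name.
#' @param n_bubbles Number of bubbles in the pool.
#' @param n_images Number of source images.
#' @param geometry A [screen_geometry()].
#' @param min_sep_deg Minimal center separation.
#' @param margin_deg Margin kept from the screen edges.
#' @param seed Integer seed.
#' @return Bubble pool data frame (`bubble_id`, `task`, `source_image_id`,
#'   `source_class`, `center_x_deg`, `center_y_deg`, `sigma_deg`,
#'   `patch_size_deg`).
#' @export
sample_bubble_pool <- function(task, n_bubbles, n_images,
                               geometry = screen_geometry(),
                               min_sep_deg = 4.0, margin_deg = 3.5, seed = 1) {
  classes <- task_classes(task)
  set.seed(seed)
  xs <- seq(margin_deg, geometry$width_deg - margin_deg, by = min_sep_deg)
  ys <- seq(margin_deg, geometry$height_deg - margin_deg, by = min_sep_deg)
  slots <- expand.grid(x = xs, y = ys)
  n_slots <- nrow(slots)
  if (n_slots < 5) stop("screen too small for a usable slot grid")

  ## bubbles per image: as even as possible, but guarantee that at least
  ## two images can host a five-bubble stimulus
  per_img <- rep(n_bubbles %/% n_images, n_images)
  rem <- n_bubbles %% n_images
  if (rem > 0) per_img[seq_len(rem)] <- per_img[seq_len(rem)] + 1L
  need5 <- min(2L, n_images)
  for (i in seq_len(need5)) {
    while (per_img[i] < min(5L, n_slots, n_bubbles - sum(per_img[seq_len(i - 1)]))) {
      cand <- which(per_img > 1)
      cand <- cand[cand > need5]
      if (!length(cand)) break
      donor <- cand[which.min(per_img[cand])]
      per_img[donor] <- per_img[donor] - 1L
      per_img[i] <- per_img[i] + 1L
    }
  }
  if (any(per_img > n_slots)) stop("not enough separated positions for the pool")

  img_ids <- sprintf("%s_img%02d", task, seq_len(n_images))
  img_class <- rep(classes, length.out = n_images)[sample.int(n_images)]
  rows <- vector("list", n_images)
  k <- 0L
  for (i in seq_len(n_images)) {
    sl <- sample.int(n_slots, per_img[i])
    idx <- k + seq_len(per_img[i])
    rows[[i]] <- data.frame(
      bubble_id = sprintf("%s_b%03d", task, idx),
      task = task,
      source_image_id = img_ids[i],
      source_class = img_class[i],
      center_x_deg = slots$x[sl],
      center_y_deg = slots$y[sl],
      sigma_deg = 1.0,
      patch_size_deg = 6.0,
      stringsAsFactors = FALSE
    )
    k <- k + per_img[i]
  }
  do.call(rbind, rows)
}

#' Sample ground truth for a bubble pool
#'
#' Draws, for every bubble, a latent response distribution from a symmetric
#' Dirichlet law (relabeled so the dominant class is the bubble's source
#' class; small concentrations give informative bubbles), a log-normal
#' feature-salience component, and a spatial component equal to a Gaussian
#' central-bias profile evaluated at the bubble's position. The true
#' empirical salience is the exponentiated weighted sum of the
#' log-components plus Gaussian log-noise — the same multiplicative
#' structure the downstream regression decomposes — normalized to sum one.
#'
#' @param pool Bubble pool from [sample_bubble_pool()].
#' @param concentration Dirichlet concentration (`Inf` gives exactly flat
#'   distributions).
#' @param weights Mixture weights `c(feature, info, spatial)` on the log
#'   scale.
#' @param log_noise_sd Sd of the Gaussian log-noise.
#' @param feature_log_sd Sd of the log-normal feature component.
#' @param bias_sd_deg Sd of the Gaussian central-bias profile generating
#'   the spatial component.
#' @param info_floor Floor on bubble information (bits) inside the log of
#'   the salience model.
#' @param geometry A [screen_geometry()].
#' @param seed Integer seed.
#' @return Object of class `ground_truth`: list with `bubbles` (data frame
#'   of components and true salience), `distributions` (matrix), `classes`,
#'   and the generator parameters.
#' @export
sample_ground_truth <- function(pool, concentration = 0.5,
                                weights = c(feature = 0.20, info = 0.35,
                                            spatial = 0.50),
                                log_noise_sd = 0.3, feature_log_sd = 0.5,
                                bias_sd_deg = 5, info_floor = 0.01,
                                geometry = screen_geometry(), seed = 1) {
  classes <- task_classes(pool$task[1])
  C <- length(classes)
  if (C < 2) stop("need at least 2 classes")
  stopifnot(concentration > 0, length(weights) == 3)
  n <- nrow(pool)
  set.seed(seed)

  if (is.infinite(concentration)) {
    dists <- matrix(1 / C, n, C)
  } else {
    g <- matrix(stats::rgamma(n * C, shape = concentration), n, C)
    g[rowSums(g) == 0, ] <- 1   # numerical underflow guard
    dists <- g / rowSums(g)
    ## relabel so the dominant class is the bubble's source class
    cls_idx <- match(pool$source_class, classes)
    for (i in seq_len(n)) {
      mx <- which.max(dists[i, ])
      if (mx != cls_idx[i]) {
        tmp <- dists[i, cls_idx[i]]
        dists[i, cls_idx[i]] <- dists[i, mx]
        dists[i, mx] <- tmp
      }
    }
  }
  dimnames(dists) <- list(pool$bubble_id, classes)
  info <- apply(dists, 1, stimulus_information)

  feature <- exp(stats::rnorm(n, 0, feature_log_sd))
  ctr <- geometry$center
  d2 <- (pool$center_x_deg - ctr["x"])^2 + (pool$center_y_deg - ctr["y"])^2
  spatial <- exp(-d2 / (2 * bias_sd_deg^2))

  ## weights act on standardized log-components, so they are comparable
  ## effect sizes regardless of the natural spread of each component
  zscore <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  logE <- weights[1] * zscore(log(feature)) +
    weights[2] * zscore(log(pmax(info, info_floor))) +
    weights[3] * zscore(log(spatial)) +
    stats::rnorm(n, 0, log_noise_sd)
  salience <- exp(logE - max(logE))
  salience <- salience / sum(salience)

  out <- list(
    bubbles = data.frame(bubble_id = pool$bubble_id,
                         feature = feature,
                         information = info,
                         spatial = spatial,
                         salience = salience,
                         stringsAsFactors = FALSE),
    distributions = dists,
    classes = classes,
    weights = weights,
    concentration = concentration,
    log_noise_sd = log_noise_sd,
    info_floor = info_floor,
    bias_sd_deg = bias_sd_deg,
    task = pool$task[1]
  )
  class(out) <- "ground_truth"
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d bubbles, %d classes (task %s)\n",
              nrow(x$bubbles), length(x$classes), x$task))
  cat(sprintf("  weights (feature, info, spatial) = (%.2f, %.2f, %.2f), log-noise sd %.2f\n",
              x$weights[1], x$weights[2], x$weights[3], x$log_noise_sd))
  invisible(x)
}

#' Generate band-limited noise images with a prescribed contrast field
#'
#' Each image is `mean_luminance` plus band-limited Gaussian noise (white
#' noise blurred with `bandlimit_sigma_deg` and standardized) multiplied
#' point-wise by the requested contrast field, so the local luminance sd
#' tracks the field. The image mean is adjusted to `mean_luminance`
#' exactly.
#'
#' @param contrast_fields Named list of matrices (desired local sd).
#' @param mean_luminance Target mean luminance.
#' @param bandlimit_sigma_deg Blur sd of the underlying noise in degrees.
#' @param px_per_deg Pixels per degree of the image grid.
#' @param seed Integer seed.
#' @return Named list of image matrices.
#' @export
generate_images <- function(contrast_fields, mean_luminance = 0.5,
                            bandlimit_sigma_deg = 0.125, px_per_deg = 8,
                            seed = 1) {
  stopifnot(is.list(contrast_fields), length(contrast_fields) > 0)
  if (any(vapply(contrast_fields, function(m) any(m < 0), logical(1)))) {
    stop("contrast fields must be nonnegative")
  }
  set.seed(seed)
  lapply(contrast_fields, function(fld) {
    noise <- matrix(stats::rnorm(length(fld)), nrow(fld), ncol(fld))
    noise <- blur_gaussian(noise, bandlimit_sigma_deg * px_per_deg)
    noise <- noise / stats::sd(noise)
    img <- fld * noise
    img - mean(img) + mean_luminance
  })
}

#' Contrast fields encoding planted feature salience at bubble centers
#'
#' Builds, for every source image of a pool, a contrast field that is a
#' uniform base plus Gaussian bumps at the image's bubble centers with
#' amplitudes proportional to the bubbles' planted feature components, so
#' that luminance contrast measured at a bubble center increases with its
#' planted feature salience.
#'
#' @param pool Bubble pool.
#' @param truth Matching [sample_ground_truth()] result.
#' @param geometry A [screen_geometry()].
#' @param px_per_deg Image resolution.
#' @param base Baseline contrast (local sd).
#' @param amplitude Maximal additional contrast at the strongest bubble.
#' @param bump_sd_deg Spatial extent of each contrast bump.
#' @return Named list of contrast-field matrices.
#' @export
planted_contrast_fields <- function(pool, truth, geometry = screen_geometry(),
                                    px_per_deg = 8, base = 0.04,
                                    amplitude = 0.20, bump_sd_deg = 1.5) {
  nxp <- round(geometry$width_deg * px_per_deg)
  nyp <- round(geometry$height_deg * px_per_deg)
  xs <- (seq_len(nxp) - 0.5) / px_per_deg
  ys <- (seq_len(nyp) - 0.5) / px_per_deg
  fmax <- max(truth$bubbles$feature)
  fields <- list()
  for (img in unique(pool$source_image_id)) {
    rows <- which(pool$source_image_id == img)
    fld <- matrix(base, nyp, nxp)
    for (r in rows) {
      f <- truth$bubbles$feature[truth$bubbles$bubble_id == pool$bubble_id[r]]
      gx <- exp(-(xs - pool$center_x_deg[r])^2 / (2 * bump_sd_deg^2))
      gy <- exp(-(ys - pool$center_y_deg[r])^2 / (2 * bump_sd_deg^2))
      fld <- fld + amplitude * (f / fmax) * outer(gy, gx)
    }
    fields[[img]] <- fld
  }
  fields
}

## truncated-Poisson (>= 1) sampler with the requested mean
rpois_trunc <- function(n, mean) {
  lambda <- if (mean > 1.5) {
    stats::uniroot(function(l) l / (1 - exp(-l)) - mean,
                   c(mean - 1, mean))$root
  } else {
    stats::uniroot(function(l) l / (1 - exp(-l)) - mean,
                   c(1e-8, 10))$root
  }
  x <- stats::rpois(n, lambda)
  while (any(x == 0)) x[x == 0] <- stats::rpois(sum(x == 0), lambda)
  x
}

## p-model response distribution of every stimulus in a set
stimulus_response_dists <- function(stimset, truth, fullfield_accuracy = 0.94) {
  classes <- truth$classes
  C <- length(classes)
  img_class <- tapply(stimset$pool$source_class, stimset$pool$source_image_id,
                      function(z) z[1])
  out <- matrix(NA_real_, nrow(stimset$stimuli), C,
                dimnames = list(stimset$stimuli$stimulus_id, classes))
  plc_split <- split(stimset$placement$bubble_id, stimset$placement$stimulus_id)
  for (i in seq_len(nrow(stimset$stimuli))) {
    sid <- stimset$stimuli$stimulus_id[i]
    if (stimset$stimuli$condition[i] == "fullfield") {
      cl <- img_class[[stimset$stimuli$source_image_id[i]]]
      p <- rep((1 - fullfield_accuracy) / (C - 1), C)
      p[match(cl, classes)] <- fullfield_accuracy
      out[i, ] <- p
    } else {
      b <- plc_split[[sid]]
      out[i, ] <- integrate_pmodel(truth$distributions[b, , drop = FALSE])
    }
  }
  out
}

#' Generate a complete synthetic bubble experiment
#'
#' Simulates all trials of the study: participants are assigned stimuli
#' (each stimulus at most once per participant), the number of analyzed
#' fixations per trial is truncated-Poisson with the design mean, fixations
#' target bubbles with probability proportional to true salience
#' (renormalized within the stimulus), landing points scatter isotropically
#' around the targeted center — with consecutive fixations on the same
#' bubble drawn from a tighter scatter so they land on average
#' `approach_deg` closer (corrective saccades) — and the classification
#' response is drawn from the p-model integration of the stimulus's true
#' bubble distributions. Fixation index 0 (near screen center) is the
#' excluded first fixation. Full-field trials draw fixations from a central
#' Gaussian and the response from a class-dominant distribution.
#'
#' @param stimsets A `stimulus_set` or named list of them (one per task).
#' @param truths Matching [sample_ground_truth()] result(s).
#' @param design An [experiment_design()].
#' @param geometry A [screen_geometry()].
#' @param fixations If `FALSE`, only responses are generated (fast path for
#'   response-model studies).
#' @param seed Integer seed; identical seeds give identical experiments.
#' @return Object of class `bubble_experiment`: list with `trials`
#'   (fixation-level table: `participant`, `stimulus`, `fix_index`,
#'   `x_deg`, `y_deg`, `response`) and `responses` (trial-level table:
#'   `participant`, `stimulus`, `task`, `response`).
#' @export
generate_experiment <- function(stimsets, truths, design = experiment_design(),
                                geometry = screen_geometry(),
                                fixations = TRUE, seed = 1) {
  if (inherits(stimsets, "stimulus_set")) {
    task <- stimsets$pool$task[1]
    stimsets <- stats::setNames(list(stimsets), task)
    truths <- stats::setNames(list(truths), task)
  }
  tasks <- names(stimsets)
  tpt <- design$trials_per_participant / length(tasks)
  set.seed(seed)

  resp_list <- vector("list", length(tasks))
  fix_list <- vector("list", length(tasks))
  for (ti in seq_along(tasks)) {
    task <- tasks[ti]
    ss <- stimsets[[task]]
    tr <- truths[[task]]
    sdist <- stimulus_response_dists(ss, tr, design$fullfield_accuracy)
    sids <- ss$stimuli$stimulus_id
    ## trial assignment: each stimulus at most once per participant when the
    ## set is large enough, with replacement otherwise (degenerate designs)
    stim_per_part <- replicate(design$n_participants,
                               sample(sids, tpt,
                                      replace = length(sids) < tpt),
                               simplify = FALSE)
    trials <- data.table::data.table(
      participant = rep(sprintf("p%03d", seq_len(design$n_participants)),
                        each = tpt),
      stimulus = unlist(stim_per_part)
    )
    ## responses, grouped by stimulus
    trials[, response := {
      p <- sdist[.BY$stimulus, ]
      sample(tr$classes, .N, replace = TRUE, prob = p)
    }, by = stimulus]
    trials[, task := task]
    resp_list[[ti]] <- data.table::copy(trials)

    if (fixations) {
      fix_list[[ti]] <- simulate_fixations(trials, ss, tr, design, geometry)
    }
  }
  responses <- as.data.frame(data.table::rbindlist(resp_list))
  out <- list(responses = responses[, c("participant", "stimulus", "task", "response")],
              trials = if (fixations)
                as.data.frame(data.table::rbindlist(fix_list)) else NULL)
  class(out) <- "bubble_experiment"
  out
}

## fixation-level simulation for one task's trials (data.table in/out)
simulate_fixations <- function(trials, stimset, truth, design, geometry) {
  n_tr <- nrow(trials)
  n_fix <- rpois_trunc(n_tr, design$mean_fixations)
  trials <- data.table::copy(trials)
  trials[, `:=`(trial_id = .I, n_fix = n_fix)]

  sal <- stats::setNames(truth$bubbles$salience, truth$bubbles$bubble_id)
  plc_split <- split(stimset$placement, stimset$placement$stimulus_id)
  ctr <- geometry$center

  ## expand to fixation rows (non-excluded)
  fx <- trials[rep(seq_len(n_tr), n_fix)]
  fx[, fix_index := seq_len(.N), by = trial_id]

  ## bubble targeting, grouped by stimulus for vectorized sampling
  fx[, bubble := {
    plc <- plc_split[[.BY$stimulus]]
    if (is.null(plc)) NA_character_
    else if (nrow(plc) == 1) rep(plc$bubble_id, .N)
    else sample(plc$bubble_id, .N, replace = TRUE, prob = sal[plc$bubble_id])
  }, by = stimulus]

  ## subsequent = same bubble as the previous fixation of the trial
  fx[, subsequent := !is.na(bubble) &
       bubble == data.table::shift(bubble, fill = "<none>"), by = trial_id]
  sd_first <- design$landing_sd_deg
  sd_sub <- max(sd_first - design$approach_deg / sqrt(pi / 2), 0.05)
  sdv <- ifelse(fx$subsequent, sd_sub, sd_first)

  ## landing positions
  bx <- rep(NA_real_, nrow(fx))
  by_ <- rep(NA_real_, nrow(fx))
  has_b <- !is.na(fx$bubble)
  if (any(has_b)) {
    key <- paste(fx$stimulus[has_b], fx$bubble[has_b])
    pk <- paste(stimset$placement$stimulus_id, stimset$placement$bubble_id)
    m <- match(key, pk)
    bx[has_b] <- stimset$placement$x_deg[m]
    by_[has_b] <- stimset$placement$y_deg[m]
  }
  ## full-field trials: central-bias fixations
  bx[!has_b] <- ctr["x"]
  by_[!has_b] <- ctr["y"]
  sdv[!has_b] <- truth$bias_sd_deg
  fx[, `:=`(
    x_deg = pmin(pmax(bx + stats::rnorm(.N, 0, sdv), 0), geometry$width_deg),
    y_deg = pmin(pmax(by_ + stats::rnorm(.N, 0, sdv), 0), geometry$height_deg)
  )]

  ## excluded first fixation near the pre-trial fixation cross
  first <- trials[, .(participant, stimulus, task, response, trial_id)]
  first[, `:=`(fix_index = 0L,
               x_deg = ctr["x"] + stats::rnorm(.N, 0, 0.3),
               y_deg = ctr["y"] + stats::rnorm(.N, 0, 0.3))]
  cols <- c("participant", "stimulus", "task", "fix_index",
            "x_deg", "y_deg", "response")
  out <- rbind(first[, ..cols], fx[, ..cols])
  data.table::setorder(out, participant, stimulus, fix_index)
  out
}

#' Generate free-viewing baseline trials
#'
#' Emulates the independent baseline study used to calibrate spatial biases
#' and the feature-to-fixation mapping: participants freely view full-field
#' images, fixations follow a Gaussian central bias and (in the Markov
#' variant) displacements follow a Gaussian saccade law. When feature maps
#' and a modulation function are supplied, fixation locations are drawn
#' with probability proportional to `central bias x feature_fun(feature)`
#' on the image grid, which gives a known generator for calibration
#' recovery. Flat biases (`central_sd_deg = Inf`) produce uniform fixations.
#'
#' @param geometry A [screen_geometry()].
#' @param n_participants Number of baseline participants.
#' @param trials_each Trials per participant.
#' @param mean_fixations Mean fixations per trial (truncated Poisson).
#' @param central_sd_deg Sd of the Gaussian central bias (`Inf` = flat).
#' @param saccade_sd_deg Sd of the Gaussian saccade displacement law.
#' @param markov If `TRUE`, fixations form a chain (displacement proposals
#'   weighted by the central bias); if `FALSE`, fixations are i.i.d. from
#'   the central bias.
#' @param images Optional named list of images viewed (cycled over trials);
#'   required for feature modulation.
#' @param feature_maps Optional [contrast_maps()] for the images.
#' @param feature_fun Optional nonnegative function of the feature value
#'   modulating fixation probability.
#' @param feature Which feature modulates (`"LC"` or `"TC"`).
#' @param seed Integer seed.
#' @return Baseline trial table (`participant`, `trial`, `image`,
#'   `fix_index`, `x_deg`, `y_deg`).
#' @export
generate_baseline <- function(geometry = screen_geometry(),
                              n_participants = 27, trials_each = 100,
                              mean_fixations = 8,
                              central_sd_deg = 5, saccade_sd_deg = 4,
                              markov = TRUE,
                              images = NULL, feature_maps = NULL,
                              feature_fun = NULL, feature = "LC", seed = 1) {
  set.seed(seed)
  ctr <- geometry$center
  n_trials <- n_participants * trials_each
  n_fix <- rpois_trunc(n_trials, mean_fixations)
  part <- rep(sprintf("b%03d", seq_len(n_participants)), each = trials_each)
  trial <- rep(seq_len(trials_each), n_participants)
  img_ids <- if (!is.null(images)) {
    rep(names(images), length.out = n_trials)[sample.int(n_trials)]
  } else rep(NA_character_, n_trials)

  central_w <- function(x, y) {
    if (is.infinite(central_sd_deg)) rep(1, length(x))
    else exp(-((x - ctr["x"])^2 + (y - ctr["y"])^2) / (2 * central_sd_deg^2))
  }

  if (!is.null(feature_fun)) {
    if (is.null(images) || is.null(feature_maps)) {
      stop("feature modulation requires images and feature_maps")
    }
    ## grid sampling: P(location) propto central bias x feature weight
    rows <- vector("list", n_trials)
    ppd <- feature_maps$px_per_deg
    wcache <- list()
    for (t in seq_len(n_trials)) {
      im <- img_ids[t]
      if (is.null(wcache[[im]])) {
        m <- feature_maps[[feature]][[im]]
        xs <- (seq_len(ncol(m)) - 0.5) / ppd
        ys <- (seq_len(nrow(m)) - 0.5) / ppd
        cw <- if (is.infinite(central_sd_deg)) {
          matrix(1, nrow(m), ncol(m))
        } else {
          exp(-outer((ys - ctr["y"])^2, (xs - ctr["x"])^2, "+") /
                (2 * central_sd_deg^2))
        }
        wcache[[im]] <- as.vector(cw * feature_fun(m))
      }
      w <- wcache[[im]]
      m <- feature_maps[[feature]][[im]]
      cell <- sample.int(length(w), n_fix[t], replace = TRUE, prob = w)
      i <- ((cell - 1L) %% nrow(m)) + 1L
      j <- ((cell - 1L) %/% nrow(m)) + 1L
      rows[[t]] <- data.frame(participant = part[t], trial = trial[t],
                              image = im, fix_index = seq_len(n_fix[t]),
                              x_deg = (j - stats::runif(n_fix[t])) / ppd,
                              y_deg = (i - stats::runif(n_fix[t])) / ppd,
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }

  ## spatial-only generator
  total <- sum(n_fix)
  xs <- numeric(total)
  ys <- numeric(total)
  if (!markov || is.infinite(central_sd_deg)) {
    ## i.i.d. draws from the central bias (flat = uniform), truncated to screen
    if (is.infinite(central_sd_deg)) {
      xs <- stats::runif(total, 0, geometry$width_deg)
      ys <- stats::runif(total, 0, geometry$height_deg)
    } else {
      need <- seq_len(total)
      while (length(need)) {
        xs[need] <- stats::rnorm(length(need), ctr["x"], central_sd_deg)
        ys[need] <- stats::rnorm(length(need), ctr["y"], central_sd_deg)
        need <- need[xs[need] < 0 | xs[need] > geometry$width_deg |
                       ys[need] < 0 | ys[need] > geometry$height_deg]
      }
    }
  } else {
    ## chain: displacement proposals accepted with prob propto central bias
    idx_end <- cumsum(n_fix)
    idx_start <- idx_end - n_fix + 1L
    ## first fixations i.i.d. from the central bias
    need <- idx_start
    while (length(need)) {
      xs[need] <- stats::rnorm(length(need), ctr["x"], central_sd_deg)
      ys[need] <- stats::rnorm(length(need), ctr["y"], central_sd_deg)
      need <- need[xs[need] < 0 | xs[need] > geometry$width_deg |
                     ys[need] < 0 | ys[need] > geometry$height_deg]
    }
    maxstep <- max(n_fix)
    for (s in 2:maxstep) {
      active <- which(n_fix >= s)
      if (!length(active)) break
      pos <- idx_start[active] + (s - 1L)
      prev <- pos - 1L
      pending <- seq_along(pos)
      px <- xs[prev]
      py <- ys[prev]
      nx <- numeric(length(pos))
      nyv <- numeric(length(pos))
      while (length(pending)) {
        cx <- px[pending] + stats::rnorm(length(pending), 0, saccade_sd_deg)
        cy <- py[pending] + stats::rnorm(length(pending), 0, saccade_sd_deg)
        ok <- cx >= 0 & cx <= geometry$width_deg &
          cy >= 0 & cy <= geometry$height_deg
        acc <- ok & stats::runif(length(pending)) < central_w(cx, cy)
        nx[pending[acc]] <- cx[acc]
        nyv[pending[acc]] <- cy[acc]
        pending <- pending[!acc]
      }
      xs[pos] <- nx
      ys[pos] <- nyv
    }
  }
  out <- data.frame(
    participant = rep(part, n_fix),
    trial = rep(trial, n_fix),
    image = rep(img_ids, n_fix),
    fix_index = unlist(lapply(n_fix, seq_len)),
    x_deg = xs, y_deg = ys,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
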