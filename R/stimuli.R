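#' Render a single bubble from an image patch
#'
#' Applies the two construction steps of a bubble to a square gray-scale
#' patch: a space-variant low-pass filter whose blur increases with
#' eccentricity from the patch center (imitating the fall-off of retinal
#' acuity, so that a single central fixation captures all of the bubble's
#' information), followed by an isotropic Gaussian mask that blends the patch
#' into the uniform gray background without visible edges.
#'
#' @param patch Square numeric matrix of luminance values in `[0, 1]`,
#'   side length `patch_size_deg * px_per_deg`.
#' @param geometry A [screen_geometry()].
#' @param sigma_deg Standard deviation of the Gaussian mask in degrees.
#' @param blur_slope Increase of the blur standard deviation (degrees of
#'   blur per degree of eccentricity). Blur is zero at the patch center.
#' @param background Background gray level the bubble is blended onto.
#' @param n_levels Number of blur levels used for the space-variant filter
#'   (per-pixel blur is linearly interpolated between levels).
#' @return Numeric matrix of the same size as `patch`.
#' @export
render_bubble <- function(patch, geometry = screen_geometry(), sigma_deg = 1,
                          blur_slope = 0.1, background = 0.5, n_levels = 6) {
  if (!is.matrix(patch) || nrow(patch) != ncol(patch)) {
    stop("patch must be a square matrix (side = patch_size_deg * px_per_deg)")
  }
  n <- nrow(patch)
  ppd <- geometry$px_per_deg
  ctr <- (n + 1) / 2
  dx <- (col(patch) - ctr) / ppd
  dy <- (row(patch) - ctr) / ppd
  ecc <- sqrt(dx^2 + dy^2)

  ## space-variant filter: blur sd grows linearly with eccentricity;
  ## computed as interpolation between uniformly blurred copies
  max_sigma <- blur_slope * max(ecc)
  if (max_sigma > 0) {
    sigmas <- seq(0, max_sigma, length.out = n_levels)
    stack <- lapply(sigmas, function(s) blur_gaussian(patch, s * ppd))
    want <- blur_slope * ecc
    idx <- pmin(findInterval(want, sigmas), n_levels - 1L)
    lo <- sigmas[idx]
    hi <- sigmas[idx + 1L]
    w <- ifelse(hi > lo, (want - lo) / (hi - lo), 0)
    filtered <- matrix(0, n, n)
    for (l in seq_len(n_levels - 1L)) {
      sel <- idx == l
      if (!any(sel)) next
      filtered[sel] <- (1 - w[sel]) * stack[[l]][sel] + w[sel] * stack[[l + 1L]][sel]
    }
    sel <- want >= sigmas[n_levels]
    if (any(sel)) filtered[sel] <- stack[[n_levels]][sel]
  } else {
    filtered <- patch
  }

  envelope <- exp(-(dx^2 + dy^2) / (2 * sigma_deg^2))
  background + envelope * (filtered - background)
}

## largest-remainder apportionment of n into integer counts with the given
## proportions; exact whenever n * p is integral
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  left <- round(n - sum(base))
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

#' Assemble a set of bubble stimuli from a bubble pool
#'
#' Combines bubbles into stimuli following the design composition: a mix of
#' single-bubble and multi-bubble stimuli (1 to 5 bubbles) in the conditions
#' *same* (all bubbles from one source image, includes the single-bubble
#' stimuli), *congruent* (different images, same class), *incongruent*
#' (images of different classes), *permuted* (a *same*-type selection with
#' the bubble positions shuffled among the chosen bubbles), and *fullfield*
#' (the unmasked source photograph). Bubble envelopes must not overlap:
#' every pair of centers within a stimulus is at least `min_sep_deg` apart.
#' A randomized balancing heuristic keeps the usage counts of individual
#' bubbles across the set approximately equal.
#'
#' @param pool Data frame of bubbles with columns `bubble_id`, `task`,
#'   `source_image_id`, `source_class`, `center_x_deg`, `center_y_deg`.
#' @param n_stimuli Number of stimuli to assemble (use multiples of 100 to
#'   reproduce the condition percentages exactly).
#' @param condition_props Named proportions of the five conditions.
#' @param count_props Named proportions of stimuli with 1..5 bubbles
#'   (single-bubble stimuli are all of condition *same*).
#' @param min_sep_deg Minimal center separation of bubbles in one stimulus.
#' @param seed Integer seed for the randomized balancing.
#' @return An object of class `stimulus_set`: a list with `stimuli` (one row
#'   per stimulus: `stimulus_id`, `task`, `condition`, `n_bubbles`,
#'   `source_image_id`) and `placement` (one row per bubble-in-stimulus:
#'   `stimulus_id`, `bubble_id`, `x_deg`, `y_deg`).
#' @export
build_stimulus_set <- function(pool, n_stimuli,
                               condition_props = c(same = 0.50, congruent = 0.15,
                                                   incongruent = 0.15,
                                                   permuted = 0.16, fullfield = 0.04),
                               count_props = c(`1` = 0.12, `2` = 0.42, `3` = 0.26,
                                               `4` = 0.14, `5` = 0.02),
                               min_sep_deg = 4.0, seed = 1) {
  stopifnot(is.data.frame(pool), nrow(pool) > 0, n_stimuli >= 1)
  if (length(unique(pool$task)) != 1) stop("pool must contain a single task")
  task <- pool$task[1]
  set.seed(seed)

  cond_n <- apportion(n_stimuli, condition_props)
  ## bubble-count proportions cover the non-fullfield share of the set
  size_n <- apportion(n_stimuli - cond_n[["fullfield"]], count_props)
  n_single <- size_n[["1"]]
  if (n_single + cond_n[["fullfield"]] > cond_n[["same"]] + cond_n[["fullfield"]]) {
    stop("infeasible design: single-bubble stimuli exceed the 'same' share")
  }
  ## multi-bubble sizes (2..5), randomly assigned to the multi-bubble stimuli
  sizes_multi <- sample(rep(2:5, times = size_n[c("2", "3", "4", "5")]))
  n_multi <- length(sizes_multi)
  cond_multi <- c(same = cond_n[["same"]] - n_single,
                  congruent = cond_n[["congruent"]],
                  incongruent = cond_n[["incongruent"]],
                  permuted = cond_n[["permuted"]])
  if (sum(cond_multi) != n_multi) {
    stop("infeasible design: condition and bubble-count proportions disagree")
  }
  conds_multi <- sample(rep(names(cond_multi), times = cond_multi))

  usage <- stats::setNames(rep(0L, nrow(pool)), pool$bubble_id)
  by_image <- split(pool$bubble_id, pool$source_image_id)
  image_class <- vapply(split(pool$source_class, pool$source_image_id),
                        function(z) z[1], character(1))
  images <- names(by_image)
  pos <- pool[, c("center_x_deg", "center_y_deg")]
  rownames(pos) <- pool$bubble_id

  sep_ok <- function(ids) {
    if (length(ids) < 2) return(TRUE)
    min(stats::dist(pos[ids, , drop = FALSE])) >= min_sep_deg
  }
  ## greedy selection of k separated bubbles from a candidate list ordered
  ## by usage; returns NULL when the constraint cannot be met
  greedy_pick <- function(cands, k, force_two_images = FALSE,
                          force_two_classes = FALSE) {
    ord <- cands[order(usage[cands] + stats::runif(length(cands), 0, 0.49))]
    chosen <- character(0)
    for (b in ord) {
      if (length(chosen) == k) break
      trial_set <- c(chosen, b)
      if (!sep_ok(trial_set)) next
      if (force_two_images && length(chosen) == k - 1) {
        imgs <- pool$source_image_id[match(trial_set, pool$bubble_id)]
        if (length(unique(imgs)) < 2) next
      }
      if (force_two_classes && length(chosen) == k - 1) {
        cls <- pool$source_class[match(trial_set, pool$bubble_id)]
        if (length(unique(cls)) < 2) next
      }
      chosen <- trial_set
    }
    if (length(chosen) == k) chosen else NULL
  }
  pick_image <- function(min_bubbles) {
    ok <- images[vapply(by_image, length, 1L) >= min_bubbles]
    if (length(ok) == 0) {
      stop(sprintf("infeasible: no source image offers %d non-overlapping bubbles",
                   min_bubbles))
    }
    mean_use <- vapply(by_image[ok], function(b) mean(usage[b]), numeric(1))
    ok[order(mean_use + stats::runif(length(ok), 0, 0.49))[1]]
  }

  stim_rows <- vector("list", n_stimuli)
  plc_rows <- vector("list", n_stimuli)
  sizes_all <- c(rep(1L, n_single), sizes_multi,
                 rep(0L, cond_n[["fullfield"]]))
  conds_all <- c(rep("same", n_single), conds_multi,
                 rep("fullfield", cond_n[["fullfield"]]))
  shuffle <- sample(length(sizes_all))
  sizes_all <- sizes_all[shuffle]
  conds_all <- conds_all[shuffle]

  for (i in seq_len(n_stimuli)) {
    k <- sizes_all[i]
    cond <- conds_all[i]
    sid <- sprintf("%s_s%04d", task, i)
    img <- NA_character_
    ids <- character(0)
    xy <- NULL
    if (cond == "fullfield") {
      img <- pick_image(1)
    } else if (cond %in% c("same", "permuted")) {
      img <- pick_image(k)
      ids <- greedy_pick(by_image[[img]], k)
      if (is.null(ids)) {
        stop(sprintf("infeasible: image %s cannot host %d bubbles at >= %.1f deg separation",
                     img, k, min_sep_deg))
      }
      xy <- pos[ids, , drop = FALSE]
      if (cond == "permuted" && k >= 2) {
        repeat {
          perm <- sample(k)
          if (any(perm != seq_len(k))) break
        }
        xy <- xy[perm, , drop = FALSE]
      }
    } else {
      ids <- greedy_pick(pool$bubble_id, k,
                         force_two_images = cond == "congruent",
                         force_two_classes = cond == "incongruent")
      if (cond == "congruent") {
        ## restrict to one class first: pick the least-used feasible class
        cls_try <- names(sort(vapply(split(usage[pool$bubble_id], pool$source_class),
                                     mean, numeric(1))))
        ids <- NULL
        for (cl in cls_try) {
          cand <- pool$bubble_id[pool$source_class == cl]
          ids <- greedy_pick(cand, k, force_two_images = TRUE)
          if (!is.null(ids)) break
        }
      }
      if (is.null(ids)) {
        stop(sprintf("infeasible: cannot assemble a %s stimulus with %d separated bubbles",
                     cond, k))
      }
      xy <- pos[ids, , drop = FALSE]
    }
    if (length(ids)) usage[ids] <- usage[ids] + 1L
    stim_rows[[i]] <- data.frame(stimulus_id = sid, task = task,
                                 condition = cond, n_bubbles = k,
                                 source_image_id = img,
                                 stringsAsFactors = FALSE)
    if (length(ids)) {
      plc_rows[[i]] <- data.frame(stimulus_id = sid, bubble_id = ids,
                                  x_deg = xy[, 1], y_deg = xy[, 2],
                                  stringsAsFactors = FALSE, row.names = NULL)
    }
  }

  out <- list(stimuli = do.call(rbind, stim_rows),
              placement = do.call(rbind, plc_rows),
              pool = pool, min_sep_deg = min_sep_deg)
  class(out) <- "stimulus_set"
  out
}

#' @export
print.stimulus_set <- function(x, ...) {
  tab <- table(x$stimuli$condition)
  cat(sprintf("<stimulus_set> %d stimuli, %d bubbles in pool (task %s)\n",
              nrow(x$stimuli), nrow(x$pool), x$pool$task[1]))
  print(tab)
  invisible(x)
}

#' Bubble usage counts of a stimulus set
#'
#' @param stimset A [build_stimulus_set()] result.
#' @return Named integer vector: number of stimuli each pool bubble appears in.
#' @export
bubble_usage <- function(stimset) {
  u <- table(factor(stimset$placement$bubble_id, levels = stimset$pool$bubble_id))
  stats::setNames(as.integer(u), names(u))
}
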