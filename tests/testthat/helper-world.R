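## Shared fixtures, all built in code.

geom <- screen_geometry()

## a small single-task world: pool, stimulus set, ground truth
make_world <- function(task = "gender", n_bubbles = 40, n_images = 10,
                       n_stimuli = 100, seed = 11, ...) {
  pool <- sample_bubble_pool(task, n_bubbles, n_images, geom, seed = seed)
  stimset <- build_stimulus_set(pool, n_stimuli, seed = seed + 1)
  truth <- sample_ground_truth(pool, seed = seed + 2, ...)
  list(pool = pool, stimset = stimset, truth = truth)
}

## a hand-built stimulus set with explicit bubble placement (no randomness)
manual_stimset <- function(task, centers, stimuli_bubbles,
                           conditions = NULL, classes = NULL) {
  ids <- names(centers)
  if (is.null(classes)) classes <- rep(task_classes(task)[1], length(ids))
  pool <- data.frame(
    bubble_id = ids, task = task,
    source_image_id = "img1", source_class = classes,
    center_x_deg = vapply(centers, `[`, numeric(1), 1),
    center_y_deg = vapply(centers, `[`, numeric(1), 2),
    sigma_deg = 1, patch_size_deg = 6, stringsAsFactors = FALSE
  )
  sids <- names(stimuli_bubbles)
  if (is.null(conditions)) conditions <- rep("same", length(sids))
  stimuli <- data.frame(
    stimulus_id = sids, task = task, condition = conditions,
    n_bubbles = vapply(stimuli_bubbles, length, integer(1)),
    source_image_id = "img1", stringsAsFactors = FALSE
  )
  placement <- do.call(rbind, lapply(sids, function(s) {
    b <- stimuli_bubbles[[s]]
    data.frame(stimulus_id = s, bubble_id = b,
               x_deg = pool$center_x_deg[match(b, pool$bubble_id)],
               y_deg = pool$center_y_deg[match(b, pool$bubble_id)],
               stringsAsFactors = FALSE)
  }))
  out <- list(stimuli = stimuli, placement = placement, pool = pool,
              min_sep_deg = 4)
  class(out) <- "stimulus_set"
  out
}

## one-row-per-fixation trial table builder
manual_trial <- function(participant, stimulus, xy, response = "male",
                         first_excluded = TRUE) {
  n <- nrow(xy)
  idx <- if (first_excluded) seq_len(n) - 1L else seq_len(n)
  data.frame(participant = participant, stimulus = stimulus,
             fix_index = idx, x_deg = xy[, 1], y_deg = xy[, 2],
             response = response, stringsAsFactors = FALSE)
}

## uniform random response distributions (rows sum to 1)
random_dists <- function(n, C) {
  m <- matrix(stats::rexp(n * C), n, C)
  m / rowSums(m)
}
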