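#' Luminance- and texture-contrast maps of a task's images
#'
#' Luminance contrast at a pixel is the Gaussian-weighted standard deviation
#' of luminance in the surrounding patch (window equal to the bubble-
#' construction Gaussian), normalized by the mean luminance over all images
#' of the task — not per image, so that contrast values remain comparable
#' across bubbles drawn from different source images. Texture contrast is
#' the Gaussian-weighted standard deviation (outer window again the bubble
#' window) of an inner luminance-contrast map computed with a window a
#' quarter of the bubble size, normalized by the task mean of that inner
#' map. A bubble's feature values are the map values at its center pixel.
#'
#' @param images Named list of gray-scale image matrices (same size).
#' @param px_per_deg Pixels per degree of the image grid.
#' @param sigma_outer_deg Outer window sd in degrees (bubble sigma).
#' @param sigma_inner_deg Inner window sd in degrees (quarter of the bubble
#'   sigma by default).
#' @return Object of class `feature_maps`: list with per-image `LC` and `TC`
#'   matrices, `task_mean_luminance`, `task_mean_LC`, and the geometry used.
#' @export
contrast_maps <- function(images, px_per_deg, sigma_outer_deg = 1.0,
                          sigma_inner_deg = sigma_outer_deg / 4) {
  stopifnot(is.list(images), length(images) > 0)
  if (is.null(names(images)) || any(names(images) == "")) {
    stop("images must be a named list")
  }
  windowed_sd <- function(img, sigma_px) {
    m1 <- blur_gaussian(img, sigma_px)
    m2 <- blur_gaussian(img^2, sigma_px)
    v <- m2 - m1^2
    v[v < 1e-12] <- 0   # roundoff on (near-)constant patches
    sqrt(v)
  }
  so <- sigma_outer_deg * px_per_deg
  si <- sigma_inner_deg * px_per_deg

  task_mean_lum <- mean(vapply(images, mean, numeric(1)))
  if (task_mean_lum <= 0) stop("cannot normalize: task mean luminance is not positive")
  lc_raw <- lapply(images, windowed_sd, sigma_px = so)
  lc_inner <- lapply(images, windowed_sd, sigma_px = si)
  task_mean_lc <- mean(vapply(lc_inner, mean, numeric(1)))
  tc_raw <- lapply(lc_inner, windowed_sd, sigma_px = so)

  LC <- lapply(lc_raw, function(m) m / task_mean_lum)
  TC <- if (task_mean_lc > 0) {
    lapply(tc_raw, function(m) m / task_mean_lc)
  } else {
    lapply(tc_raw, function(m) m * 0)
  }
  out <- list(LC = LC, TC = TC,
              task_mean_luminance = task_mean_lum,
              task_mean_LC = task_mean_lc,
              px_per_deg = px_per_deg,
              sigma_outer_deg = sigma_outer_deg,
              sigma_inner_deg = sigma_inner_deg)
  class(out) <- "feature_maps"
  out
}

#' Read a feature-map value at screen coordinates
#'
#' @param maps A [contrast_maps()] result.
#' @param image_id Name of the image.
#' @param x_deg,y_deg Coordinates in degrees (top-left origin).
#' @param feature `"LC"` or `"TC"`.
#' @return Map value at the nearest pixel (clamped to the image).
#' @export
feature_value_at <- function(maps, image_id, x_deg, y_deg, feature = c("LC", "TC")) {
  feature <- match.arg(feature)
  m <- maps[[feature]][[image_id]]
  if (is.null(m)) stop(sprintf("no %s map for image '%s'", feature, image_id))
  i <- pmin(pmax(round(y_deg * maps$px_per_deg), 1), nrow(m))
  j <- pmin(pmax(round(x_deg * maps$px_per_deg), 1), ncol(m))
  m[cbind(i, j)]
}

#' Equal-population bins over observed feature values
#'
#' Places `k - 1` internal bin edges at midpoints between adjacent order
#' statistics so that the number of available locations falling into each
#' bin is constant (within one location when `length(values)` is not a
#' multiple of `k`). With massive ties an edge may coincide with the tie
#' block; duplicated edges are collapsed and the binning flagged as unequal.
#'
#' @param values Numeric vector of available feature values.
#' @param k Number of bins.
#' @return Object of class `feature_bins`: list with `edges` (internal
#'   boundaries), `k`, `range`, `flagged_unequal`.
#' @export
equal_population_bins <- function(values, k = 20) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (length(unique(values)) < k) {
    stop(sprintf("need at least %d distinct values for %d bins", k, k))
  }
  s <- sort(values)
  cut_idx <- round(seq_len(k - 1) * n / k)
  edges <- (s[cut_idx] + s[pmin(cut_idx + 1L, n)]) / 2
  flagged <- anyDuplicated(edges) > 0
  edges <- unique(edges)
  out <- list(edges = edges, k = length(edges) + 1L,
              range = range(values), flagged_unequal = flagged)
  class(out) <- "feature_bins"
  out
}

#' Bin index of feature values
#'
#' @param values Numeric vector.
#' @param bins A [equal_population_bins()] result.
#' @return Integer bin indices in `1..bins$k` (values outside the calibrated
#'   range fall into the nearest terminal bin).
#' @export
bin_of <- function(values, bins) {
  findInterval(values, bins$edges) + 1L
}

#' Conditional fixation probability per feature bin
#'
#' Estimates, from baseline free-viewing fixations, the probability that a
#' fixated location falls into each feature bin. Because the bins are
#' equal-population over available image locations, the feature prior is
#' constant and Bayes' rule reduces to the (bias-corrected) distribution of
#' fixations over bins. The spatial viewing bias is removed by weighting
#' each fixation inversely by the central-bias density at its location, so
#' that the mapping reflects feature selection only.
#'
#' @param feature_values Feature value at each baseline fixation.
#' @param bins A [equal_population_bins()] result built from the available
#'   locations of the same images.
#' @param bias_weights Optional positive weights per fixation (typically
#'   `1 / central-bias density`); `NULL` for unweighted.
#' @param floor Probability floor for bins with no fixations.
#' @return Object of class `bin_mapping`: list with `prob` (length `k`,
#'   sums to 1), `bins`, `n_fixations`.
#' @export
feature_fixation_mapping <- function(feature_values, bins, bias_weights = NULL,
                                     floor = 1e-6) {
  stopifnot(length(feature_values) > 0)
  if (is.null(bias_weights)) bias_weights <- rep(1, length(feature_values))
  stopifnot(length(bias_weights) == length(feature_values), all(bias_weights > 0))
  b <- bin_of(feature_values, bins)
  w <- vapply(seq_len(bins$k), function(i) sum(bias_weights[b == i]), numeric(1))
  p <- w / sum(w)
  p <- pmax(p, floor)
  p <- p / sum(p)
  out <- list(prob = p, bins = bins, n_fixations = length(feature_values))
  class(out) <- "bin_mapping"
  out
}

#' Stimulus-dependent salience of bubbles
#'
#' The stimulus-dependent (feature-based) salience of a bubble is the
#' product of the conditional fixation probabilities for its luminance
#' contrast and its texture contrast, both read at the bubble's center on
#' the source full-field image and mapped through the baseline-calibrated
#' bin mappings. Assuming independent contributions of the two features,
#' log salience is additive in the two log probabilities.
#'
#' @param pool Bubble pool data frame (`bubble_id`, `source_image_id`,
#'   `center_x_deg`, `center_y_deg`).
#' @param maps A [contrast_maps()] result for the task's images.
#' @param mapping_lc,mapping_tc [feature_fixation_mapping()] results for
#'   luminance and texture contrast.
#' @return A `salience_table` (measure `"feature"`), one row per bubble.
#' @export
stimulus_dependent_salience <- function(pool, maps, mapping_lc, mapping_tc) {
  lc <- mapply(function(img, x, y) feature_value_at(maps, img, x, y, "LC"),
               pool$source_image_id, pool$center_x_deg, pool$center_y_deg)
  tc <- mapply(function(img, x, y) feature_value_at(maps, img, x, y, "TC"),
               pool$source_image_id, pool$center_x_deg, pool$center_y_deg)
  p_lc <- mapping_lc$prob[bin_of(lc, mapping_lc$bins)]
  p_tc <- mapping_tc$prob[bin_of(tc, mapping_tc$bins)]
  salience_table(stats::setNames(p_lc * p_tc, pool$bubble_id), "feature")
}
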