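#' Assign the fixations of one trial to bubbles
#'
#' Each non-excluded fixation (fixation index 0, the one carried over from
#' the pre-trial fixation cross, is excluded from all analyses) is assigned
#' to the nearest bubble center if that center is no more than
#' `max_dist_deg` away; otherwise to the screen center if within
#' `center_radius_deg` of it; otherwise it counts as scattered. Ties between
#' equidistant bubble centers are broken by the lexicographically smallest
#' bubble id so that assignment is deterministic.
#'
#' @param trial Data frame with the fixations of a single trial (columns
#'   `stimulus`, `fix_index`, `x_deg`, `y_deg`).
#' @param stimset A [build_stimulus_set()] result containing the trial's
#'   stimulus.
#' @param geometry A [screen_geometry()].
#' @param max_dist_deg Assignment radius around bubble centers.
#' @param center_radius_deg Radius of the screen-center region.
#' @return List with `assignment` (per-fixation data frame: `fix_index`,
#'   `category` in bubble/center/scattered/excluded, `bubble_id`,
#'   `dist_deg`), `counts` (named fixation counts per bubble of the
#'   stimulus), `n_center`, `n_scattered`.
#' @export
assign_fixations <- function(trial, stimset, geometry = screen_geometry(),
                             max_dist_deg = 3.0, center_radius_deg = 1.5) {
  sid <- unique(trial$stimulus)
  if (length(sid) != 1) stop("trial must contain exactly one stimulus id")
  if (!sid %in% stimset$stimuli$stimulus_id) {
    stop(sprintf("stimulus '%s' is not part of the stimulus set", sid))
  }
  plc <- stimset$placement[stimset$placement$stimulus_id == sid, , drop = FALSE]
  asn <- assign_fixation_table(trial, stimset, geometry,
                               max_dist_deg, center_radius_deg)
  counts <- table(factor(asn$bubble_id[asn$category == "bubble"],
                         levels = sort(plc$bubble_id)))
  list(assignment = as.data.frame(asn[, c("fix_index", "category",
                                          "bubble_id", "dist_deg")]),
       counts = stats::setNames(as.integer(counts), names(counts)),
       n_center = sum(asn$category == "center"),
       n_scattered = sum(asn$category == "scattered"))
}

## Vectorized assignment over a full trial table. Returns a data.table with
## the trial columns plus category / bubble_id / dist_deg.
assign_fixation_table <- function(trials, stimset, geometry = screen_geometry(),
                                  max_dist_deg = 3.0, center_radius_deg = 1.5) {
  dt <- data.table::as.data.table(trials)
  dt[, `:=`(.fid = .I,
            category = "scattered",
            bubble_id = NA_character_,
            dist_deg = NA_real_)]
  plc <- data.table::as.data.table(stimset$placement)
  cand <- merge(dt[, .(.fid, stimulus, x_deg, y_deg)], plc,
                by.x = "stimulus", by.y = "stimulus_id",
                allow.cartesian = TRUE)
  if (nrow(cand) > 0) {
    cand[, d := sqrt((x_deg.x - x_deg.y)^2 + (y_deg.x - y_deg.y)^2)]
    data.table::setorder(cand, .fid, d, bubble_id)
    best <- cand[, .SD[1], by = .fid]
    best <- best[d <= max_dist_deg]
    dt[best$.fid, `:=`(category = "bubble",
                       bubble_id = best$bubble_id,
                       dist_deg = best$d)]
  }
  ctr <- geometry$center
  dcen <- sqrt((dt$x_deg - ctr["x"])^2 + (dt$y_deg - ctr["y"])^2)
  dt[category != "bubble" & dcen <= center_radius_deg, category := "center"]
  dt[fix_index == 0, category := "excluded"]
  dt[, .fid := NULL]
  dt[]
}

#' First versus subsequent fixation distances to bubble centers
#'
#' Splits bubble-assigned fixations into "first" fixations (entering a
#' bubble from outside it) and "subsequent" fixations (consecutive
#' fixations within the same bubble), and compares their distance-to-center
#' distributions with each other and with the reference distribution that
#' would result if fixations were sampled from the Gaussian window used to
#' construct the bubbles (radial distances Rayleigh(`sigma_deg`), median
#' `sigma_deg * sqrt(2 log 2)`, i.e. 1.18 degrees at sigma 1).
#' Two-sample comparisons use the Kolmogorov-Smirnov test.
#'
#' @param trials Trial table (`participant`, `stimulus`, `fix_index`,
#'   `x_deg`, `y_deg`).
#' @param stimset A [build_stimulus_set()] result.
#' @param geometry A [screen_geometry()].
#' @param sigma_deg Standard deviation of the bubble-construction Gaussian.
#' @param max_dist_deg,center_radius_deg Assignment parameters, see
#'   [assign_fixations()].
#' @return List with the two group medians, the closed-form reference
#'   median, the per-group sample sizes, the mean paired first-minus-
#'   subsequent distance, and the three KS comparisons (`NA` when a group
#'   is empty).
#' @export
fixation_distance_stats <- function(trials, stimset,
                                    geometry = screen_geometry(),
                                    sigma_deg = 1.0, max_dist_deg = 3.0,
                                    center_radius_deg = 1.5) {
  asn <- assign_fixation_table(trials, stimset, geometry,
                               max_dist_deg, center_radius_deg)
  asn <- asn[category != "excluded"]
  data.table::setorder(asn, participant, stimulus, fix_index)
  asn[, prev_bubble := data.table::shift(bubble_id),
      by = .(participant, stimulus)]
  bub <- asn[category == "bubble"]
  bub[, kind := ifelse(!is.na(prev_bubble) & prev_bubble == bubble_id,
                       "subsequent", "first")]
  d_first <- bub$dist_deg[bub$kind == "first"]
  d_sub <- bub$dist_deg[bub$kind == "subsequent"]

  ## paired first -> immediately following subsequent fixation in same bubble
  bub[, next_kind := data.table::shift(kind, -1), by = .(participant, stimulus)]
  bub[, next_dist := data.table::shift(dist_deg, -1), by = .(participant, stimulus)]
  bub[, next_bubble := data.table::shift(bubble_id, -1), by = .(participant, stimulus)]
  pairs <- bub[kind == "first" & !is.na(next_kind) & next_kind == "subsequent" &
                 next_bubble == bubble_id]
  paired_approach <- if (nrow(pairs)) mean(pairs$dist_deg - pairs$next_dist) else NA_real_

  p_rayleigh <- function(q) 1 - exp(-q^2 / (2 * sigma_deg^2))
  ks_or_na <- function(x, y) {
    if (length(x) < 2 || (is.numeric(y) && length(y) < 2)) return(NULL)
    suppressWarnings(stats::ks.test(x, y))
  }
  list(
    median_first = if (length(d_first)) stats::median(d_first) else NA_real_,
    median_subsequent = if (length(d_sub)) stats::median(d_sub) else NA_real_,
    reference_median = rayleigh_median(sigma_deg),
    n_first = length(d_first),
    n_subsequent = length(d_sub),
    mean_paired_approach = paired_approach,
    ks_first_vs_subsequent = ks_or_na(d_first, d_sub),
    ks_first_vs_reference = if (length(d_first) >= 2)
      suppressWarnings(stats::ks.test(d_first, p_rayleigh)) else NULL,
    ks_subsequent_vs_reference = if (length(d_sub) >= 2)
      suppressWarnings(stats::ks.test(d_sub, p_rayleigh)) else NULL,
    distances = list(first = d_first, subsequent = d_sub)
  )
}
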