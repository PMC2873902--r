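## Discretization of the screen used for bias maps and trajectory
## simulation. `res` is cells per degree; maps are ny x nx matrices of cell
## masses summing to 1 (row = y, column = x, top-left origin).
bias_grid <- function(geometry = screen_geometry(), res = 3) {
  nx <- max(2L, round(geometry$width_deg * res))
  ny <- max(2L, round(geometry$height_deg * res))
  list(res = res, nx = nx, ny = ny, geometry = geometry)
}

grid_cell <- function(grid, x_deg, y_deg) {
  j <- pmin(pmax(ceiling(x_deg * grid$res), 1L), grid$nx)
  i <- pmin(pmax(ceiling(y_deg * grid$res), 1L), grid$ny)
  cbind(i, j)
}

## smooth a mass grid with a Gaussian kernel (sd in cells), renormalize to 1
smooth_mass <- function(m, sd_cells) {
  if (sd_cells > 0) m <- blur_gaussian(m, sd_cells)
  m / sum(m)
}

#' Estimate central-bias and saccade bias maps from baseline data
#'
#' From free-viewing baseline trials, computes the distribution of fixation
#' locations in screen coordinates (central-bias map) and the distribution
#' of fixation-to-fixation displacement vectors (saccade map). Each trial
#' contributes its own normalized histogram, so trials are weighted equally
#' regardless of how many fixations they contain; the trial average is
#' convolved with a Gaussian kernel (sd `smooth_sd_deg`) and normalized to
#' total mass one. Trials with fewer than two fixations contribute nothing
#' to the saccade map.
#'
#' @param baseline_trials Data frame (`participant`, `trial` or `stimulus`,
#'   `fix_index`, `x_deg`, `y_deg`).
#' @param geometry A [screen_geometry()].
#' @param res Grid resolution in cells per degree.
#' @param smooth_sd_deg Smoothing kernel sd in degrees.
#' @return Object of class `bias_maps`: list with `central` (ny x nx mass
#'   grid, sum 1), `saccade` ((2 ny - 1) x (2 nx - 1) mass grid over
#'   displacements, sum 1, zero displacement at the center cell), `grid`,
#'   `smooth_sd_deg`, `n_trials`.
#' @export
estimate_bias_maps <- function(baseline_trials, geometry = screen_geometry(),
                               res = 3, smooth_sd_deg = 0.5) {
  stopifnot(nrow(baseline_trials) > 0)
  grid <- bias_grid(geometry, res)
  dt <- data.table::as.data.table(baseline_trials)
  key <- if ("trial" %in% names(dt)) c("participant", "trial") else c("participant", "stimulus")
  data.table::setorderv(dt, c(key, "fix_index"))
  ij <- grid_cell(grid, dt$x_deg, dt$y_deg)
  dt[, `:=`(ci = ij[, 1], cj = ij[, 2])]

  central <- matrix(0, grid$ny, grid$nx)
  cen <- dt[, .(n = .N), by = c(key, "ci", "cj")]
  cen[, tot := sum(n), by = key]
  acc <- cen[, .(m = sum(n / tot)), by = .(ci, cj)]
  central[cbind(acc$ci, acc$cj)] <- acc$m
  n_trials <- nrow(unique(dt[, ..key]))
  central <- smooth_mass(central / n_trials, smooth_sd_deg * res)

  dt[, `:=`(di = ci - data.table::shift(ci), dj = cj - data.table::shift(cj)),
     by = key]
  sac_dt <- dt[!is.na(di)]
  saccade <- matrix(0, 2 * grid$ny - 1, 2 * grid$nx - 1)
  if (nrow(sac_dt) > 0) {
    sc <- sac_dt[, .(n = .N), by = c(key, "di", "dj")]
    sc[, tot := sum(n), by = key]
    sacc <- sc[, .(m = sum(n / tot)), by = .(di, dj)]
    saccade[cbind(sacc$di + grid$ny, sacc$dj + grid$nx)] <- sacc$m
    n_sac_trials <- nrow(unique(sac_dt[, ..key]))
    saccade <- smooth_mass(saccade / n_sac_trials, smooth_sd_deg * res)
  }
  out <- list(central = central, saccade = saccade, grid = grid,
              smooth_sd_deg = smooth_sd_deg, n_trials = n_trials)
  class(out) <- "bias_maps"
  out
}

#' @export
print.bias_maps <- function(x, ...) {
  cat(sprintf("<bias_maps> %d x %d grid (%.1f cells/deg), smoothing %.2f deg, %d trials\n",
              x$grid$ny, x$grid$nx, x$grid$res, x$smooth_sd_deg, x$n_trials))
  invisible(x)
}

#' Central-bias mass at screen locations
#'
#' @param maps A [estimate_bias_maps()] result (or compatible `bias_maps`).
#' @param x_deg,y_deg Coordinates in degrees.
#' @return Cell mass of the central-bias map at each location.
#' @export
bias_density_at <- function(maps, x_deg, y_deg) {
  ij <- grid_cell(maps$grid, x_deg, y_deg)
  maps$central[ij]
}

#' Bubble-position map of a stimulus
#'
#' Point-wise maximum of the per-bubble Gaussian envelopes (value 1 at each
#' bubble center) on the bias grid; the maximum avoids double-counting where
#' envelope tails meet. Full-field stimuli (no bubbles) yield a uniform map.
#'
#' @param stimset A [build_stimulus_set()] result.
#' @param stimulus_id Stimulus identifier.
#' @param grid A bias grid (from a `bias_maps` object).
#' @param sigma_deg Envelope standard deviation in degrees.
#' @return ny x nx matrix with values in (0, 1].
#' @export
bubble_position_map <- function(stimset, stimulus_id, grid, sigma_deg = 1.0) {
  plc <- stimset$placement[stimset$placement$stimulus_id == stimulus_id, , drop = FALSE]
  if (nrow(plc) == 0) return(matrix(1, grid$ny, grid$nx))
  cx <- (seq_len(grid$nx) - 0.5) / grid$res
  cy <- (seq_len(grid$ny) - 0.5) / grid$res
  mask <- matrix(0, grid$ny, grid$nx)
  for (b in seq_len(nrow(plc))) {
    d2 <- outer((cy - plc$y_deg[b])^2, (cx - plc$x_deg[b])^2, "+")
    mask <- pmax(mask, exp(-d2 / (2 * sigma_deg^2)))
  }
  mask
}

#' Simulate gaze trajectories from spatial biases alone
#'
#' Generative scanpath model: for each trial, an intermediate map is the
#' point-wise product of the central-bias map and the stimulus's bubble-
#' position map; each next fixation is drawn from the intermediate map
#' multiplied point-wise with the saccade map shifted so its center lies at
#' the current fixation (the screen center for the trial's first fixation),
#' renormalized to total mass one. The model is first-order: no inhibition
#' of return. As many fixations are drawn per trial as in the corresponding
#' original trial; the first simulated fixation is flagged with index 0 and
#' excluded from analyses, mirroring the convention for real trials.
#'
#' @param stimset A [build_stimulus_set()] result.
#' @param maps A [estimate_bias_maps()] result.
#' @param trial_lengths Data frame (`participant`, `stimulus`, `n_fix`):
#'   number of non-excluded fixations to draw per trial.
#' @param sigma_deg Bubble envelope sd for the position map.
#' @param seed Integer seed.
#' @return Simulated trial table (`participant`, `stimulus`, `fix_index`,
#'   `x_deg`, `y_deg`), fixation index 0 flagged excluded downstream.
#' @export
simulate_trajectories <- function(stimset, maps, trial_lengths,
                                  sigma_deg = 1.0, seed = 1) {
  stopifnot(all(c("participant", "stimulus", "n_fix") %in% names(trial_lengths)))
  grid <- maps$grid
  set.seed(seed)
  ny <- grid$ny
  nx <- grid$nx
  sac <- maps$saccade
  ctr_cell <- grid_cell(grid, grid$geometry$center["x"], grid$geometry$center["y"])

  ord <- order(trial_lengths$stimulus)
  tl <- trial_lengths[ord, , drop = FALSE]
  res_list <- vector("list", length(unique(tl$stimulus)))
  li <- 0L
  for (sid in unique(tl$stimulus)) {
    mask <- bubble_position_map(stimset, sid, grid, sigma_deg)
    inter <- maps$central * mask
    if (sum(inter) <= 0) inter <- maps$central  # bubbles outside bias support
    rows <- which(tl$stimulus == sid)
    n_tot <- sum(tl$n_fix[rows] + 1L)
    xs <- numeric(n_tot); ys <- numeric(n_tot)
    idxs <- integer(n_tot); ps <- character(n_tot); k <- 0L
    for (r in rows) {
      cur_i <- ctr_cell[1]; cur_j <- ctr_cell[2]
      for (f in 0:tl$n_fix[r]) {
        win <- sac[(ny - cur_i + 1):(2 * ny - cur_i),
                   (nx - cur_j + 1):(2 * nx - cur_j)]
        p <- inter * win
        if (sum(p) <= 0) p <- inter
        cell <- sample.int(ny * nx, 1L, prob = p)
        cur_i <- ((cell - 1L) %% ny) + 1L
        cur_j <- ((cell - 1L) %/% ny) + 1L
        k <- k + 1L
        xs[k] <- (cur_j - stats::runif(1)) / grid$res
        ys[k] <- (cur_i - stats::runif(1)) / grid$res
        idxs[k] <- f
        ps[k] <- tl$participant[r]
      }
    }
    li <- li + 1L
    res_list[[li]] <- data.frame(participant = ps, stimulus = sid,
                                 fix_index = idxs, x_deg = xs, y_deg = ys,
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res_list)
  rownames(out) <- NULL
  out
}

#' Spatial-bias salience of bubbles
#'
#' Runs the fixation-fraction computation and the global salience solver on
#' trajectories simulated from spatial biases alone, yielding a per-bubble
#' salience that reflects only bubble positions, the central fixation bias,
#' and saccade statistics — transformed to a global scale exactly like the
#' empirical salience of real trials.
#'
#' @param sim_trials Output of [simulate_trajectories()].
#' @param stimset The stimulus set that was simulated.
#' @param geometry A [screen_geometry()].
#' @param ... Passed to [observed_fractions()].
#' @return A `salience_table` (measure `"spatial"`).
#' @export
spatial_bias_salience <- function(sim_trials, stimset,
                                  geometry = screen_geometry(), ...) {
  fr <- observed_fractions(sim_trials, stimset, geometry, ...)
  st <- solve_salience(fr, stimset)
  attr(st, "measure") <- "spatial"
  st
}
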