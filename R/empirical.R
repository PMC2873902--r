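#' Mean observed fixation fractions per stimulus and bubble
#'
#' For every trial with at least one bubble-assigned fixation, computes the
#' fraction of that trial's bubble-assigned fixations landing on each bubble
#' of the stimulus (bubbles of the stimulus that received none count as 0),
#' then averages the fractions over all trials of the stimulus. Trials in
#' which no fixation was assigned to any bubble do not contribute.
#'
#' @param trials Trial table (`participant`, `stimulus`, `fix_index`,
#'   `x_deg`, `y_deg`).
#' @param stimset A [build_stimulus_set()] result.
#' @param geometry A [screen_geometry()].
#' @param max_dist_deg,center_radius_deg Assignment parameters, see
#'   [assign_fixations()].
#' @return Data frame with `stimulus_id`, `bubble_id`, `fraction`,
#'   `n_trials` (trials contributing to the average).
#' @export
observed_fractions <- function(trials, stimset, geometry = screen_geometry(),
                               max_dist_deg = 3.0, center_radius_deg = 1.5) {
  asn <- assign_fixation_table(trials, stimset, geometry,
                               max_dist_deg, center_radius_deg)
  bub <- asn[category == "bubble",
             .(n_fix = .N), by = .(participant, stimulus, bubble_id)]
  if (nrow(bub) == 0) stop("no bubble-assigned fixations")
  tot <- bub[, .(tot = sum(n_fix)), by = .(participant, stimulus)]
  plc <- data.table::as.data.table(stimset$placement)
  grid <- merge(tot, plc, by.x = "stimulus", by.y = "stimulus_id",
                allow.cartesian = TRUE)
  grid <- merge(grid, bub, by = c("participant", "stimulus", "bubble_id"),
                all.x = TRUE)
  grid[is.na(n_fix), n_fix := 0L]
  grid[, frac := n_fix / tot]
  out <- grid[, .(fraction = mean(frac), n_trials = .N),
              by = .(stimulus, bubble_id)]
  data.table::setnames(out, "stimulus", "stimulus_id")
  data.table::setorder(out, stimulus_id, bubble_id)
  as.data.frame(out)
}

#' Context-independent empirical salience from fixation fractions
#'
#' Under the assumption that the ratio of fixations falling on two bubbles
#' does not depend on which other bubbles are present, every observed mean
#' fraction yields one linear equation
#' `E_A - fraction_S(A) * sum(E_B, B in S) = 0` in the global empirical
#' saliences E. The saliences are the weighted least-squares solution of the
#' stacked system under the scale constraint that all saliences of the task
#' sum to one (the constraint is eliminated by substitution, so consistent
#' systems are solved exactly). Each equation is weighted by the number of
#' trials behind its fraction. Components that come out negative are clipped
#' to a small positive floor (the downstream log transform requires
#' positivity) and the solution renormalized; bubbles absent from the
#' fraction table are assigned the floor and flagged.
#'
#' @param fractions Output of [observed_fractions()].
#' @param stimset A [build_stimulus_set()] result.
#' @param floor Positivity floor for clipped / disconnected bubbles.
#' @return Object of class `salience_table`: data frame `bubble_id`,
#'   `salience`, with attributes `residual_norm`, `n_clipped`,
#'   `disconnected` (bubble ids) and `measure = "empirical"`.
#' @export
solve_salience <- function(fractions, stimset, floor = 1e-6) {
  stopifnot(nrow(fractions) > 0)
  bubbles <- sort(unique(fractions$bubble_id))
  n <- length(bubbles)
  if (n == 1) {
    E <- stats::setNames(1, bubbles)
    res <- salience_table(E, "empirical")
    attr(res, "residual_norm") <- 0
    attr(res, "n_clipped") <- 0L
    attr(res, "disconnected") <- character(0)
    return(res)
  }
  plc <- stimset$placement
  ## coefficient matrix: one row per (stimulus, bubble) fraction
  M <- matrix(0, nrow(fractions), n, dimnames = list(NULL, bubbles))
  for (i in seq_len(nrow(fractions))) {
    S <- fractions$stimulus_id[i]
    inS <- plc$bubble_id[plc$stimulus_id == S]
    M[i, inS] <- -fractions$fraction[i]
    M[i, fractions$bubble_id[i]] <- M[i, fractions$bubble_id[i]] + 1
  }
  w <- sqrt(fractions$n_trials)
  ## eliminate the constraint sum(E) = 1: E_n = 1 - sum(E_1..E_{n-1})
  A <- (M[, -n, drop = FALSE] - M[, n]) * w
  b <- -M[, n] * w
  fit <- stats::lm.fit(A, b)
  E <- c(fit$coefficients, 1 - sum(fit$coefficients))
  E[is.na(E)] <- 0
  names(E) <- bubbles
  residual_norm <- sqrt(sum((M %*% E)^2 * fractions$n_trials))

  disconnected <- setdiff(stimset$pool$bubble_id, bubbles)
  if (length(disconnected)) {
    E <- c(E, stats::setNames(rep(floor, length(disconnected)), disconnected))
  }
  n_clipped <- sum(E < floor)
  E <- pmax(E, floor)
  E <- E / sum(E)
  E <- E[order(names(E))]

  res <- salience_table(E, "empirical")
  attr(res, "residual_norm") <- residual_norm
  attr(res, "n_clipped") <- as.integer(n_clipped)
  attr(res, "disconnected") <- disconnected
  res
}

salience_table <- function(values, measure) {
  df <- data.frame(bubble_id = names(values), salience = as.numeric(values),
                   stringsAsFactors = FALSE, row.names = NULL)
  attr(df, "measure") <- measure
  class(df) <- c("salience_table", "data.frame")
  df
}

#' @export
print.salience_table <- function(x, ...) {
  cat(sprintf("<salience_table> measure '%s', %d bubbles (sum %.4f)\n",
              attr(x, "measure"), nrow(x), sum(x$salience)))
  NextMethod()
}

#' Reconstruction accuracy of fixation fractions from salience
#'
#' From the global saliences, the fraction of fixations expected on bubble A
#' of stimulus S is `E_A / sum(E_B, B in S)`. Accuracy is
#' `100 * (1 - mean |predicted - observed|)` over all (stimulus, bubble)
#' cells of the fraction table — how faithfully the context-independent
#' salience reproduces the observed per-stimulus fixation splits.
#'
#' @param salience A [solve_salience()] result (or any `salience_table`).
#' @param fractions Output of [observed_fractions()].
#' @param stimset A [build_stimulus_set()] result.
#' @return Accuracy in percent.
#' @export
reconstruction_accuracy <- function(salience, fractions, stimset) {
  if (nrow(fractions) == 0) stop("empty fraction table")
  E <- stats::setNames(salience$salience, salience$bubble_id)
  plc <- stimset$placement
  pred <- vapply(seq_len(nrow(fractions)), function(i) {
    S <- fractions$stimulus_id[i]
    inS <- plc$bubble_id[plc$stimulus_id == S]
    E[fractions$bubble_id[i]] / sum(E[inS])
  }, numeric(1))
  100 * (1 - mean(abs(pred - fractions$fraction)))
}
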