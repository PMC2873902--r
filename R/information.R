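#' Stimulus or bubble information of a response distribution
#'
#' Information is the maximal attainable entropy minus the Shannon entropy
#' (base 2) of the response distribution: a flat distribution over C classes
#' carries 0 bit, a unanimous one carries `log2(C)` bit (2 bit for the
#' four-class expression task, 1 bit for the two-class tasks).
#'
#' @param dist Numeric probability vector over the task's classes.
#' @return Information in bits, in `[0, log2(length(dist))]`.
#' @export
stimulus_information <- function(dist) {
  if (length(dist) == 0) stop("empty response distribution")
  if (any(dist < 0) || abs(sum(dist) - 1) > 1e-9) {
    stop("dist must be a probability vector summing to 1")
  }
  log2(length(dist)) - entropy_bits(dist)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Probabilistic information integration (p-model)
#'
#' Combines the response distributions of the individual bubbles of a
#' stimulus into the stimulus response distribution under the assumption
#' that the bubbles carry independent evidence: the component-wise product
#' of the distributions, renormalized over classes. The flat distribution is
#' the identity of this operation, which is commutative and associative; a
#' zero component is absorbing for its class.
#'
#' @param dists List of probability vectors (all of the same length), or a
#'   matrix with one distribution per row.
#' @return The integrated probability vector.
#' @export
integrate_pmodel <- function(dists) {
  m <- as_dist_matrix(dists)
  z <- apply(m, 2, prod)
  s <- sum(z)
  if (s <= 0) {
    stop("degenerate evidence: the class-wise product of the distributions is zero everywhere")
  }
  z / s
}

#' Max-model information integration
#'
#' Alternative integration rule that keeps only the most informative
#' bubble's response distribution; ties are broken by the first index.
#'
#' @inheritParams integrate_pmodel
#' @return The probability vector of the most informative input.
#' @export
integrate_maxmodel <- function(dists) {
  m <- as_dist_matrix(dists)
  info <- apply(m, 1, stimulus_information)
  m[which.max(info), ]
}

as_dist_matrix <- function(dists) {
  m <- if (is.matrix(dists)) dists else do.call(rbind, lapply(dists, as.numeric))
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9)) {
    stop("each distribution must be nonnegative and sum to 1")
  }
  m
}

#' Global maximum-likelihood fit of per-bubble response distributions
#'
#' Estimates one response distribution per bubble from the classification
#' responses to all stimuli simultaneously, assuming that responses to a
#' stimulus are i.i.d. draws from the p-model integration of its bubbles'
#' distributions. Bubbles are parameterized by `C - 1` unconstrained reals
#' through a normalized exponential (softmax), giving
#' `n_bubbles * (C - 1)` free parameters; the log-likelihood is maximized
#' by seeded multi-start BFGS with an analytic gradient and the best start
#' is kept. Probabilities are floored at `floor` inside the likelihood to
#' keep it finite at the boundary.
#'
#' @param responses Data frame with one classification response per trial:
#'   columns `stimulus`, `response`.
#' @param stimset A [build_stimulus_set()] result (full-field stimuli are
#'   ignored: they have no bubbles).
#' @param classes Character vector of the task's classes.
#' @param n_starts Number of random restarts.
#' @param floor Probability floor inside the likelihood.
#' @param reltol Convergence tolerance on the relative log-likelihood change.
#' @param seed Integer seed for the restarts.
#' @return Object of class `bubble_fit`: list with `distributions` (matrix,
#'   one row per bubble, columns = classes), `information` (bits per
#'   bubble), `log_likelihood`, `n_parameters`, `n_equations` (scalar
#'   equation counts under both the `C` and `C - 1` components-per-stimulus
#'   conventions), `converged`, `classes`.
#' @export
fit_bubble_distributions <- function(responses, stimset, classes,
                                     n_starts = 5, floor = 1e-6,
                                     reltol = 1e-8, seed = 1) {
  C <- length(classes)
  stopifnot(C >= 2)
  plc <- stimset$placement
  resp <- responses[responses$stimulus %in% plc$stimulus_id, , drop = FALSE]
  if (nrow(resp) == 0) stop("no responses to bubble stimuli")
  if (!all(resp$response %in% classes)) {
    stop("responses contain labels outside the task's class set")
  }
  bubbles <- sort(unique(plc$bubble_id))
  nb <- length(bubbles)

  ## aggregate: one row per (stimulus, response) with a count
  agg <- data.table::as.data.table(resp)[, .N, by = .(stimulus, response)]
  stim_ids <- sort(unique(agg$stimulus))
  ns <- length(stim_ids)
  ## stimulus x bubble incidence
  plc_used <- plc[plc$stimulus_id %in% stim_ids, , drop = FALSE]
  A <- matrix(0, ns, nb, dimnames = list(stim_ids, bubbles))
  A[cbind(match(plc_used$stimulus_id, stim_ids),
          match(plc_used$bubble_id, bubbles))] <- 1
  ## response count matrix (stimulus x class)
  Ncnt <- matrix(0, ns, C, dimnames = list(stim_ids, classes))
  Ncnt[cbind(match(agg$stimulus, stim_ids), match(agg$response, classes))] <- agg$N

  theta_to_p <- function(theta) {
    th <- cbind(matrix(theta, nb, C - 1), 0)
    e <- exp(th - apply(th, 1, max))
    e / rowSums(e)
  }
  negloglik <- function(theta) {
    p <- theta_to_p(theta)
    logq <- A %*% log(pmax(p, floor))          # ns x C
    P <- exp(logq - apply(logq, 1, max))
    P <- P / rowSums(P)
    -sum(Ncnt * log(pmax(P, floor)))
  }
  neggrad <- function(theta) {
    p <- theta_to_p(theta)
    logq <- A %*% log(pmax(p, floor))
    P <- exp(logq - apply(logq, 1, max))
    P <- P / rowSums(P)
    ## d loglik / d theta_{b,c} = sum over stimuli containing b of
    ##   (count of class-c responses - n_responses * P[c])
    R <- Ncnt - rowSums(Ncnt) * P              # ns x C
    G <- t(A) %*% R                            # nb x C
    -as.vector(G[, seq_len(C - 1), drop = FALSE])
  }

  set.seed(seed)
  best <- NULL
  conv <- FALSE
  for (s in seq_len(n_starts)) {
    init <- stats::rnorm(nb * (C - 1), sd = if (s == 1) 0 else 0.5)
    opt <- stats::optim(init, negloglik, neggrad, method = "BFGS",
                        control = list(maxit = 500, reltol = reltol))
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      conv <- opt$convergence == 0
    }
  }
  if (!conv) warning("bubble-distribution fit did not fully converge; best iterate returned")

  p <- theta_to_p(best$par)
  dimnames(p) <- list(bubbles, classes)
  info <- apply(p, 1, stimulus_information)
  out <- list(
    distributions = p,
    information = info,
    log_likelihood = -best$value,
    n_parameters = nb * (C - 1),
    n_equations = c(per_class = ns * C, per_free_class = ns * (C - 1)),
    n_stimuli = ns,
    n_bubbles = nb,
    converged = conv,
    classes = classes
  )
  class(out) <- "bubble_fit"
  out
}

#' @export
print.bubble_fit <- function(x, ...) {
  cat(sprintf("<bubble_fit> %d bubbles, %d classes: %d free parameters, %d stimuli\n",
              x$n_bubbles, length(x$classes), x$n_parameters, x$n_stimuli))
  cat(sprintf("  log-likelihood %.2f (%s)\n", x$log_likelihood,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  bubble information: median %.3f bit, range [%.3f, %.3f]\n",
              stats::median(x$information), min(x$information), max(x$information)))
  invisible(x)
}

#' Predicted stimulus information as a function of bubble count
#'
#' Draws, for each bubble count, random samples from a pool of single-bubble
#' response distributions (independently of image class), integrates each
#' sample with the p-model, and averages the resulting stimulus information
#' over replicates — the model curve of information versus number of
#' bubbles.
#'
#' @param dists Matrix of single-bubble response distributions (rows).
#' @param n_bubbles Vector of bubble counts to evaluate.
#' @param reps Number of random draws per count.
#' @param seed Integer seed.
#' @return Data frame with `n_bubbles`, `mean_information`.
#' @export
predict_info_vs_count <- function(dists, n_bubbles = 1:5, reps = 1000, seed = 1) {
  m <- as_dist_matrix(dists)
  set.seed(seed)
  mean_info <- vapply(n_bubbles, function(n) {
    vals <- vapply(seq_len(reps), function(r) {
      idx <- sample.int(nrow(m), n, replace = nrow(m) < n)
      stimulus_information(integrate_pmodel(m[idx, , drop = FALSE]))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  data.frame(n_bubbles = n_bubbles, mean_information = mean_info)
}

#' Prediction error of stimulus information and its sampling lower bound
#'
#' Compares, per stimulus, the information of the p-model prediction from
#' fitted bubble distributions with the information of the observed response
#' proportions, and reports the mean absolute error in bits. The lower bound
#' is obtained by re-sampling responses from the fitted stimulus
#' distributions with the real per-stimulus trial counts: even a perfect
#' model incurs this much error from finite-sample entropy fluctuation.
#'
#' @param fit A [fit_bubble_distributions()] result.
#' @param responses Observed responses (`stimulus`, `response`).
#' @param stimset The stimulus set used for the fit.
#' @param reps Monte-Carlo replicates for the lower bound.
#' @param seed Integer seed.
#' @return List with `mean_abs_error_bits`, `lower_bound_bits`, and the
#'   per-stimulus table.
#' @export
info_prediction_error <- function(fit, responses, stimset, reps = 100, seed = 1) {
  classes <- fit$classes
  C <- length(classes)
  plc <- stimset$placement
  resp <- responses[responses$stimulus %in% plc$stimulus_id, , drop = FALSE]
  agg <- data.table::as.data.table(resp)[, .N, by = .(stimulus, response)]
  stim_ids <- sort(unique(agg$stimulus))
  cnt <- matrix(0, length(stim_ids), C, dimnames = list(stim_ids, classes))
  cnt[cbind(match(agg$stimulus, stim_ids), match(agg$response, classes))] <- agg$N

  pred <- t(vapply(stim_ids, function(s) {
    b <- plc$bubble_id[plc$stimulus_id == s]
    integrate_pmodel(fit$distributions[b, , drop = FALSE])
  }, numeric(C)))
  info_pred <- apply(pred, 1, stimulus_information)
  obs_prop <- cnt / rowSums(cnt)
  info_obs <- apply(obs_prop, 1, stimulus_information)
  err <- mean(abs(info_pred - info_obs))

  set.seed(seed)
  n_per <- rowSums(cnt)
  lb <- mean(vapply(seq_len(reps), function(r) {
    sim_info <- vapply(seq_along(stim_ids), function(i) {
      k <- stats::rmultinom(1, n_per[i], pred[i, ])[, 1]
      stimulus_information(k / sum(k))
    }, numeric(1))
    mean(abs(info_pred - sim_info))
  }, numeric(1)))

  list(mean_abs_error_bits = err, lower_bound_bits = lb,
       per_stimulus = data.frame(stimulus = stim_ids,
                                 info_predicted = info_pred,
                                 info_observed = info_obs,
                                 n_responses = n_per))
}

#' Bootstrap percentile confidence interval for a cell statistic
#'
#' Resamples the values of one cell (e.g. the stimulus-information values of
#' all trials with a given bubble count and condition) with replacement and
#' returns the percentile interval of the statistic.
#'
#' @param x Numeric vector of per-trial (or per-stimulus) values in the cell.
#' @param statistic Function mapping a numeric vector to a scalar.
#' @param reps Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return List with `estimate`, `lower`, `upper`, `level`. A singleton cell
#'   yields `NA` bounds (interval undefined).
#' @export
bootstrap_ci <- function(x, statistic = mean, reps = 1000, level = 0.95, seed = 1) {
  est <- statistic(x)
  if (length(x) < 2) {
    return(list(estimate = est, lower = NA_real_, upper = NA_real_,
                level = level, n = length(x)))
  }
  set.seed(seed)
  idx <- matrix(sample.int(length(x), length(x) * reps, replace = TRUE),
                nrow = length(x))
  stats_boot <- apply(idx, 2, function(i) statistic(x[i]))
  qs <- stats::quantile(stats_boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(estimate = est, lower = qs[1], upper = qs[2], level = level,
       n = length(x))
}

#' Monte-Carlo test of position effects on response distributions
#'
#' For each pair of response count vectors — the responses to a stimulus and
#' to its position-permuted version — tests whether both are consistent with
#' draws from one common multinomial. The statistic is the maximal absolute
#' difference of class proportions; its null distribution is simulated by
#' drawing both sides from the pooled proportions at the observed sample
#' sizes. The statistic is nonnegative, so the `level` region is `[0, q]`
#' with `q` the `level` quantile of the null. Returns the fraction of pairs
#' whose observed statistic lies inside the null region.
#'
#' @param pairs List of pairs; each element is a list/length-2 list of two
#'   integer count vectors over the same classes.
#' @param reps Null simulations per pair.
#' @param level Size of the null region.
#' @param seed Integer seed.
#' @return List with `fraction_inside`, per-pair statistics and thresholds.
#' @export
permutation_position_test <- function(pairs, reps = 1000, level = 0.95, seed = 1) {
  stopifnot(length(pairs) > 0)
  set.seed(seed)
  res <- t(vapply(pairs, function(pr) {
    a <- pr[[1]]
    b <- pr[[2]]
    stopifnot(length(a) == length(b), sum(a) > 0, sum(b) > 0)
    stat <- max(abs(a / sum(a) - b / sum(b)))
    pool <- (a + b) / sum(a + b)
    sa <- stats::rmultinom(reps, sum(a), pool) / sum(a)
    sb <- stats::rmultinom(reps, sum(b), pool) / sum(b)
    null_stats <- apply(abs(sa - sb), 2, max)
    thr <- stats::quantile(null_stats, level, names = FALSE)
    c(stat = stat, threshold = thr)
  }, numeric(2)))
  inside <- res[, "stat"] <= res[, "threshold"]
  list(fraction_inside = mean(inside),
       statistics = res[, "stat"],
       thresholds = res[, "threshold"],
       inside = inside)
}
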