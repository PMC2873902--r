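#' Floored natural-log transform
#'
#' Natural logarithm of `pmax(values, floor)`. Salience and information
#' measures are nonnegative and right-skewed; the log transform makes their
#' distributions more normal before correlation analysis, and the floor
#' keeps zero values finite. The number of floored values is recorded in the
#' `"n_floored"` attribute.
#'
#' @param values Nonnegative numeric vector.
#' @param floor Positive floor applied before the log.
#' @return Log-transformed vector with attribute `n_floored`.
#' @export
log_transform <- function(values, floor = 1e-6) {
  if (any(values < 0, na.rm = TRUE)) stop("values must be nonnegative")
  out <- log(pmax(values, floor))
  attr(out, "n_floored") <- sum(values < floor, na.rm = TRUE)
  out
}

#' Pearson correlation with t-test
#'
#' Product-moment correlation between two vectors with the two-sided t-test
#' on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return List with `r`, `p`, `n`, `df`.
#' @export
correlation_tests <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance")
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       df = unname(ct$parameter))
}

#' Multivariate linear regression of salience on the three predictors
#'
#' Ordinary least squares with intercept of the outcome on all predictor
#' columns; reports the coefficient table, R-squared, and the overall
#' F-test.
#'
#' @param X Data frame or matrix of predictors (one row per bubble).
#' @param y Outcome vector.
#' @return List with `coefficients`, `r_squared`, `f_statistic`, `f_p`,
#'   `fitted`, `residuals`, `model` (the `lm` fit).
#' @export
multivariate_regression <- function(X, y) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y), nrow(X) > ncol(X) + 1)
  dat <- cbind(.y = y, X)
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  if (any(is.na(stats::coef(fit)))) {
    warning("collinear predictors: rank-deficient fit, pseudo-solution returned")
  }
  fp <- if (!is.null(sm$fstatistic)) {
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  } else NA_real_
  list(coefficients = stats::coef(fit),
       r_squared = sm$r.squared,
       f_statistic = unname(sm$fstatistic[1]),
       f_p = fp,
       fitted = stats::fitted(fit),
       residuals = stats::residuals(fit),
       model = fit)
}

#' Semi-partial correlations of each predictor with the outcome
#'
#' For predictor j, regresses j on the remaining predictors (with
#' intercept) and correlates the residuals with the outcome. The squared
#' semi-partial correlation equals the unique contribution of the predictor
#' to the full model's R-squared (`sr_j^2 = R2_full - R2_without_j`).
#' Significance is a two-sided t-test on the residual correlation.
#'
#' @param X Data frame or matrix of predictors.
#' @param y Outcome vector.
#' @return Data frame with `predictor`, `sr`, `p`.
#' @export
semipartial_correlations <- function(X, y) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y), ncol(X) >= 2)
  res <- lapply(names(X), function(j) {
    others <- X[, setdiff(names(X), j), drop = FALSE]
    rj <- stats::residuals(stats::lm(X[[j]] ~ ., data = others))
    ct <- correlation_tests(rj, y)
    data.frame(predictor = j, sr = ct$r, p = ct$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Full correlation analysis of the three salience predictors
#'
#' For one task, assembles the log-transformed predictor matrix (stimulus-
#' dependent salience, bubble information, spatial-bias salience) and the
#' log-transformed empirical salience, and reports the pairwise
#' correlations, semi-partial correlations, and the multivariate regression
#' — the per-task decomposition of what drives overt attention.
#'
#' @param empirical A `salience_table` of empirical saliences.
#' @param feature A `salience_table` of stimulus-dependent saliences.
#' @param information Named vector of bubble information in bits (or a
#'   `salience_table`).
#' @param spatial A `salience_table` of spatial-bias saliences.
#' @param info_floor Floor applied to bubble information before the log
#'   (information near zero is common and would otherwise dominate the log
#'   scale).
#' @param floor Floor for the salience measures.
#' @return Object of class `attention_analysis`: list with `table` (one row
#'   per predictor: r, p_r, sr, p_sr), `r_squared`, `f_p`, `n`, and the
#'   underlying matrices.
#' @export
attention_analysis <- function(empirical, feature, information, spatial,
                               info_floor = 0.01, floor = 1e-6) {
  as_named <- function(s) {
    if (inherits(s, "salience_table") || is.data.frame(s)) {
      stats::setNames(s$salience, s$bubble_id)
    } else s
  }
  e <- as_named(empirical)
  f <- as_named(feature)
  i <- as_named(information)
  s <- as_named(spatial)
  ids <- Reduce(intersect, list(names(e), names(f), names(i), names(s)))
  if (length(ids) < 5) stop("too few bubbles shared by all four measures")
  y <- log_transform(e[ids], floor)
  X <- data.frame(
    feature = as.numeric(log_transform(f[ids], floor)),
    information = as.numeric(log_transform(i[ids], info_floor)),
    spatial = as.numeric(log_transform(s[ids], floor))
  )
  pw <- lapply(X, function(x) correlation_tests(x, as.numeric(y)))
  sp <- semipartial_correlations(X, as.numeric(y))
  mv <- multivariate_regression(X, as.numeric(y))
  tab <- data.frame(
    predictor = names(X),
    r = vapply(pw, `[[`, numeric(1), "r"),
    p_r = vapply(pw, `[[`, numeric(1), "p"),
    sr = sp$sr,
    p_sr = sp$p,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- list(table = tab, r_squared = mv$r_squared, f_p = mv$f_p,
              n = length(ids), X = X, y = as.numeric(y), bubbles = ids,
              model = mv)
  class(out) <- "attention_analysis"
  out
}

#' @export
print.attention_analysis <- function(x, ...) {
  stars <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
  cat(sprintf("<attention_analysis> %d bubbles: R^2 = %.3f (F-test p = %.2g)\n",
              x$n, x$r_squared, x$f_p))
  tab <- x$table
  for (k in seq_len(nrow(tab))) {
    cat(sprintf("  %-12s r = %6.3f%-2s  sr = %6.3f%-2s\n",
                tab$predictor[k], tab$r[k], stars(tab$p_r[k]),
                tab$sr[k], stars(tab$p_sr[k])))
  }
  invisible(x)
}
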