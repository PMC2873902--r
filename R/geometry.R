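#' Screen geometry of the experimental display
#'
#' Describes the display in degrees of visual angle. The defaults correspond
#' to a 1024 x 786 pixel CRT viewed at a distance giving 33 pixels per degree,
#' i.e. roughly 31.0 x 23.8 degrees of usable field. Coordinates are degrees
#' with the origin at the top-left corner, x increasing rightward and y
#' increasing downward; all distances are Euclidean in degrees.
#'
#' @param width_px,height_px Display size in pixels.
#' @param px_per_deg Pixels per degree of visual angle.
#' @return An object of class `screen_geometry` with fields `width_deg`,
#'   `height_deg`, `px_per_deg`, `center` (screen center in degrees).
#' @export
screen_geometry <- function(width_px = 1024, height_px = 786, px_per_deg = 33) {
  stopifnot(width_px > 0, height_px > 0, px_per_deg > 0)
  g <- list(
    width_deg = width_px / px_per_deg,
    height_deg = height_px / px_per_deg,
    px_per_deg = px_per_deg,
    width_px = as.integer(round(width_px)),
    height_px = as.integer(round(height_px))
  )
  g$center <- c(x = g$width_deg / 2, y = g$height_deg / 2)
  class(g) <- "screen_geometry"
  g
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %.2f x %.2f deg (%d x %d px, %.0f px/deg)\n",
              x$width_deg, x$height_deg, x$width_px, x$height_px, x$px_per_deg))
  invisible(x)
}

#' Classification tasks and their response classes
#'
#' The four classification tasks of the bubble paradigm and their class sets:
#' facial expression (4 classes), gender, human influence, and scenic
#' openness (2 classes each).
#'
#' @param task Task name, one of `"expression"`, `"gender"`, `"influence"`,
#'   `"space"`.
#' @return Character vector of class labels for the task.
#' @export
task_classes <- function(task) {
  sets <- list(
    expression = c("happy", "sad", "fearful", "disgusted"),
    gender = c("male", "female"),
    influence = c("present", "absent"),
    space = c("closed", "open")
  )
  task <- match.arg(task, names(sets))
  sets[[task]]
}

## 1-d Gaussian kernel, truncated at +/- 4 sd, normalized to sum 1
gaussian_kernel_1d <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(seq(-half, half), sd = sigma_px)
  k / sum(k)
}

## Row-stochastic 1-d smoothing matrix (n x n): boundary-renormalized
## truncated Gaussian. Used as S %*% img %*% t(S) for separable blur so the
## weighted means stay proper averages at image borders.
smoothing_matrix <- function(n, sigma_px) {
  if (sigma_px <= 0) return(diag(n))
  k <- gaussian_kernel_1d(sigma_px)
  half <- (length(k) - 1L) / 2L
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    keep <- j >= 1 & j <= n
    S[i, j[keep]] <- k[keep]
  }
  S / rowSums(S)
}

## Separable Gaussian blur of a matrix with boundary renormalization.
blur_gaussian <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  Sr <- smoothing_matrix(nrow(img), sigma_px)
  Sc <- smoothing_matrix(ncol(img), sigma_px)
  Sr %*% img %*% t(Sc)
}

## Median radial distance of an isotropic bivariate Gaussian with sd sigma:
## the radius is Rayleigh(sigma), whose median is sigma * sqrt(2 log 2).
#' Median radial distance of an isotropic bivariate Gaussian
#'
#' Closed form for the median distance from the center of samples drawn from
#' an isotropic bivariate Gaussian with standard deviation `sigma` per axis
#' (the radius is Rayleigh distributed): `sigma * sqrt(2 * log(2))`. For the
#' bubble-construction window (`sigma = 1` degree) this is 1.18 degrees.
#'
#' @param sigma Per-axis standard deviation in degrees.
#' @return Median radial distance in degrees.
#' @export
rayleigh_median <- function(sigma = 1) {
  stopifnot(sigma > 0)
  sigma * sqrt(2 * log(2))
}
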