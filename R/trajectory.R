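#' Construct a movement trajectory
#'
#' A trajectory is one uniformly sampled scalar curve \eqn{\beta(t)} on
#' \eqn{[0, T]}: typically the y-axis gyroscope signal (angular velocity,
#' deg/s) of a single repetition of an activity of daily living, recorded at
#' the dominant wrist. Angular velocity is used because it is insensitive to
#' limb length, which varies widely in growing children.
#'
#' @param values numeric vector of angular-velocity samples (deg/s); all
#'   finite, at least 8 samples.
#' @param grid sample times; must be strictly increasing and uniformly
#'   spaced (relative tolerance 1e-9). Defaults to a unit-interval grid.
#' @param subject_id opaque subject label.
#' @param visit integer visit number (>= 1).
#' @param activity one of `"curl"`, `"knock"`, `"other"`.
#' @return an object of class `"trajectory"` with fields `grid`, `values`,
#'   `subject_id`, `visit`, `activity`.
#' @examples
#' b <- trajectory(sin(seq(0, pi, length.out = 50)))
#' print(b)
#' @export
trajectory <- function(values, grid = seq(0, 1, length.out = length(values)),
                       subject_id = NA_character_, visit = 1L,
                       activity = c("other", "curl", "knock")) {
  activity <- match.arg(activity)
  values <- as.numeric(values)
  grid <- as.numeric(grid)
  check_grid(grid)
  if (length(values) != length(grid))
    stop("`values` and `grid` lengths differ", call. = FALSE)
  if (length(values) < 8L)
    stop("a trajectory needs at least 8 samples", call. = FALSE)
  if (!all(is.finite(values)))
    stop("trajectory values must all be finite", call. = FALSE)
  structure(list(grid = grid, values = values,
                 subject_id = as.character(subject_id),
                 visit = as.integer(visit), activity = activity),
            class = "trajectory")
}

# Validate a strictly increasing uniform grid.
check_grid <- function(grid) {
  if (length(grid) < 2L || !all(is.finite(grid)))
    stop("grid must be a finite vector of length >= 2", call. = FALSE)
  d <- diff(grid)
  if (any(d <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  if (max(d) - min(d) > 1e-9 * max(abs(d)))
    stop("grid must be uniformly spaced", call. = FALSE)
  invisible(grid)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s / visit %d / %s: %d samples on [%g, %g], range [%.3g, %.3g]\n",
              x$subject_id, x$visit, x$activity, length(x$grid),
              x$grid[1], x$grid[length(x$grid)],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ...,
                            xlab = "time", ylab = "angular velocity") {
  graphics::plot(x$grid, x$values, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Resample a trajectory onto a common uniform grid
#'
#' Linearly interpolates the curve onto `n_grid` uniform samples and, by
#' default, rescales the time axis to the unit interval. Rescaling loses no
#' information here: gyroscope values are rates, so speed differences remain
#' visible in the amplitude after the time axis is normalized.
#'
#' @param x a [trajectory()].
#' @param n_grid number of output samples (default 200).
#' @param rescale_time rescale the grid to `[0, 1]` (default `TRUE`).
#' @return a [trajectory()] on the new grid.
#' @export
resample_trajectory <- function(x, n_grid = 200L, rescale_time = TRUE) {
  stopifnot(inherits(x, "trajectory"))
  T0 <- x$grid[1]; T1 <- x$grid[length(x$grid)]
  new_t <- seq(T0, T1, length.out = n_grid)
  v <- stats::approx(x$grid, x$values, xout = new_t)$y
  g <- if (rescale_time) seq(0, 1, length.out = n_grid) else new_t
  trajectory(v, g, subject_id = x$subject_id, visit = x$visit,
             activity = x$activity)
}

#' Smooth a noisy trajectory
#'
#' Fits a cubic smoothing spline (generalized cross-validation by default)
#' and returns the smoothed curve on the same grid. Measurement noise is
#' greatly amplified by the differentiation inside [to_srvf()], so noisy
#' sensor curves should be smoothed before elastic analysis; on noise-free
#' curves the GCV spline is essentially an identity.
#'
#' @param x a [trajectory()].
#' @param df optional fixed equivalent degrees of freedom; `NULL` (default)
#'   selects the penalty by GCV.
#' @return a [trajectory()] with smoothed values.
#' @export
smooth_trajectory <- function(x, df = NULL) {
  stopifnot(inherits(x, "trajectory"))
  fit <- if (is.null(df)) stats::smooth.spline(x$grid, x$values)
  else stats::smooth.spline(x$grid, x$values, df = df)
  trajectory(stats::predict(fit, x$grid)$y, x$grid,
             subject_id = x$subject_id, visit = x$visit,
             activity = x$activity)
}

#' Discrete L2 norm of a sampled function
#'
#' Approximates \eqn{\|f\| = \sqrt{\int_0^T f(t)^2 dt}} from uniform samples
#' by the finite sum \eqn{\sqrt{(T/J)\sum_j f(t_j)^2}} with \eqn{J} the
#' number of samples.
#'
#' @param values samples of `f`.
#' @param grid the uniform sample grid (used only for its span `T`).
#' @return nonnegative scalar.
#' @examples
#' l2_norm(rep(1, 100), seq(0, 1, length.out = 100))  # == 1
#' @export
l2_norm <- function(values, grid = seq(0, 1, length.out = length(values))) {
  J <- length(values)
  T_ <- grid[length(grid)] - grid[1]
  sqrt(T_ / J * sum(values^2))
}

# Discrete L2 inner product with the same (T/J) weighting as l2_norm().
l2_inner <- function(f, g, grid) {
  J <- length(f)
  T_ <- grid[length(grid)] - grid[1]
  T_ / J * sum(f * g)
}
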