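#' Construct a time-warping function
#'
#' A warping function (phase) \eqn{\gamma : [0, T] \to [0, T]} is a
#' boundary-pinned, strictly increasing reparameterization of the time axis
#' (a positive diffeomorphism, sampled on the grid). Warps carry the rate at
#' which a movement was performed; composing a curve with a warp changes its
#' timing but not its shape.
#'
#' @param values warped times; `values[1]` must equal `grid[1]` and the last
#'   value must equal the last grid point, and all forward differences must
#'   be positive.
#' @param grid uniform sample grid, as in [trajectory()].
#' @return an object of class `"warp_fn"`.
#' @examples
#' g <- seq(0, 1, length.out = 100)
#' w <- warp_fn(g + 0.2 * sin(pi * g) / pi, g)
#' @export
warp_fn <- function(values, grid = seq(0, 1, length.out = length(values))) {
  values <- as.numeric(values)
  check_grid(grid)
  if (length(values) != length(grid))
    stop("`values` and `grid` lengths differ", call. = FALSE)
  n <- length(values)
  if (values[1] != grid[1] || values[n] != grid[n])
    stop("warp endpoints must be pinned to the grid endpoints", call. = FALSE)
  if (any(diff(values) <= 0))
    stop("warp must be strictly increasing", call. = FALSE)
  structure(list(grid = grid, values = values), class = "warp_fn")
}

#' Identity warp on a uniform grid
#' @param n number of samples.
#' @param T_max end of the time interval (default 1).
#' @return a [warp_fn()] with \eqn{\gamma(t) = t}.
#' @export
identity_warp <- function(n = 200L, T_max = 1) {
  g <- seq(0, T_max, length.out = n)
  warp_fn(g, g)
}

#' Invert a warping function
#'
#' Numerical inverse by swapping the roles of abscissa and ordinate and
#' re-interpolating onto the grid; \eqn{\gamma^{-1}(\gamma(t)) \approx t}.
#'
#' @param gamma a [warp_fn()].
#' @return a [warp_fn()] sampling \eqn{\gamma^{-1}}.
#' @export
invert_warp <- function(gamma) {
  stopifnot(inherits(gamma, "warp_fn"))
  g <- gamma$grid
  v <- stats::approx(gamma$values, g, xout = g, rule = 2)$y
  n <- length(g)
  v[1] <- g[1]; v[n] <- g[n]
  v <- enforce_increasing(v, g)
  warp_fn(v, g)
}

#' Compose two warping functions
#'
#' Returns \eqn{\gamma_1 \circ \gamma_2}, i.e. `gamma1(gamma2(t))`, sampled
#' on the common grid.
#'
#' @param gamma1,gamma2 [warp_fn()] objects on the same grid.
#' @return a [warp_fn()].
#' @export
compose_warps <- function(gamma1, gamma2) {
  stopifnot(inherits(gamma1, "warp_fn"), inherits(gamma2, "warp_fn"))
  g <- gamma1$grid
  v <- stats::approx(g, gamma1$values, xout = gamma2$values, rule = 2)$y
  n <- length(g)
  v[1] <- g[1]; v[n] <- g[n]
  v <- enforce_increasing(v, g)
  warp_fn(v, g)
}

# Repair ties introduced by interpolation so the warp stays strictly
# increasing; nudges are below interpolation error and endpoint-safe.
enforce_increasing <- function(v, g) {
  n <- length(v)
  eps <- (g[n] - g[1]) * 1e-12
  for (i in 2:n) if (v[i] <= v[i - 1]) v[i] <- v[i - 1] + eps
  if (v[n] > g[n]) {
    # rescale the (tiny) overshoot back onto [g1, gn]
    v <- g[1] + (v - g[1]) * (g[n] - g[1]) / (v[n] - g[1])
    v[n] <- g[n]
  }
  v
}

#' @export
print.warp_fn <- function(x, ...) {
  dev <- max(abs(x$values - x$grid))
  cat(sprintf("<warp_fn> %d samples on [%g, %g], max |gamma(t) - t| = %.4g\n",
              length(x$grid), x$grid[1], x$grid[length(x$grid)], dev))
  invisible(x)
}

#' Warp a trajectory in time
#'
#' Computes \eqn{\beta \circ \gamma} by linear interpolation onto the common
#' grid. Endpoint values are preserved because admissible warps pin the
#' boundary.
#'
#' @param x a [trajectory()].
#' @param gamma a [warp_fn()] on the same grid.
#' @return a [trajectory()].
#' @export
warp_trajectory <- function(x, gamma) {
  stopifnot(inherits(x, "trajectory"), inherits(gamma, "warp_fn"))
  if (length(x$grid) != length(gamma$grid))
    stop("trajectory and warp must share a grid", call. = FALSE)
  v <- stats::approx(x$grid, x$values, xout = gamma$values, rule = 2)$y
  trajectory(v, x$grid, subject_id = x$subject_id, visit = x$visit,
             activity = x$activity)
}
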