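#' Square-root velocity function (SRVF) of a trajectory
#'
#' The SRVF of a curve \eqn{\beta} is
#' \eqn{q(t) = \mathrm{sign}(\dot\beta(t))\sqrt{|\dot\beta(t)|}}. Under this
#' representation the elastic alignment problem becomes an L2 problem: time
#' warping acts on SRVFs by the norm-preserving group action
#' \eqn{(q \circ \gamma)\sqrt{\dot\gamma}}, which is what makes the
#' amplitude distance warp-invariant.
#'
#' The derivative is taken by centred finite differences in the interior and
#' one-sided differences at the endpoints. Optional pre-smoothing (a small
#' moving average) is available for noisy sensor data and is off by default.
#'
#' @param curve a [trajectory()].
#' @param smooth integer half-width of an optional moving-average
#'   pre-smoother applied to the values before differentiation; `0` (the
#'   default) disables smoothing.
#' @return an object of class `"srvf"` with fields `grid`, `values` and
#'   `origin_value` (\eqn{\beta(0)}, retained so the map can be inverted).
#' @seealso [from_srvf()] for the inverse map.
#' @export
to_srvf <- function(curve, smooth = 0L) {
  stopifnot(inherits(curve, "trajectory"))
  v <- curve$values
  if (smooth > 0L) {
    k <- 2L * as.integer(smooth) + 1L
    v <- stats::filter(v, rep(1 / k, k), sides = 2)
    v <- as.numeric(v)
    # fall back to the raw samples where the window does not fit
    nas <- is.na(v)
    v[nas] <- curve$values[nas]
  }
  dv <- finite_diff(v, curve$grid)
  q <- sign(dv) * sqrt(abs(dv))
  structure(list(grid = curve$grid, values = q, origin_value = curve$values[1]),
            class = "srvf")
}

# centred differences in the interior, one-sided at the ends
finite_diff <- function(v, grid) {
  n <- length(v)
  h <- grid[2] - grid[1]
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / h
  d[n] <- (v[n] - v[n - 1]) / h
  if (n > 2) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
  d
}

# cumulative trapezoidal integral of y over uniform grid, starting at 0
cumtrapz_uniform <- function(y, grid) {
  h <- grid[2] - grid[1]
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2 * h))
}

#' Invert the SRVF map
#'
#' Reconstructs the trajectory as
#' \eqn{\beta(t) = \beta(0) + \int_0^t \mathrm{sign}(q)\,q^2\,ds}
#' by cumulative trapezoidal quadrature. Needed to visualize principal-mode
#' traversals, which are constructed in SRVF space.
#'
#' @param srvf an `"srvf"` object.
#' @return a [trajectory()].
#' @export
from_srvf <- function(srvf) {
  stopifnot(inherits(srvf, "srvf"))
  q <- srvf$values
  v <- srvf$origin_value + cumtrapz_uniform(sign(q) * q^2, srvf$grid)
  trajectory(v, srvf$grid)
}

#' @export
print.srvf <- function(x, ...) {
  cat(sprintf("<srvf> %d samples on [%g, %g], ||q|| = %.4g, origin %.4g\n",
              length(x$grid), x$grid[1], x$grid[length(x$grid)],
              l2_norm(x$values, x$grid), x$origin_value))
  invisible(x)
}

#' Group action of a warp on an SRVF
#'
#' Implements \eqn{(q, \gamma) \mapsto (q \circ \gamma)\sqrt{\dot\gamma}},
#' the SRVF of the warped curve. The action is an isometry: it preserves the
#' L2 norm of `q` (change of variables), which is the algebraic fact behind
#' warp invariance of the amplitude distance.
#'
#' @param q an `"srvf"` object.
#' @param gamma a [warp_fn()] on the same grid.
#' @return an `"srvf"` object.
#' @export
warp_srvf <- function(q, gamma) {
  stopifnot(inherits(q, "srvf"), inherits(gamma, "warp_fn"))
  if (length(q$grid) != length(gamma$grid))
    stop("srvf and warp must share a grid", call. = FALSE)
  qv <- stats::approx(q$grid, q$values, xout = gamma$values, rule = 2)$y
  gdot <- finite_diff(gamma$values, gamma$grid)
  gdot[gdot < 0] <- 0
  structure(list(grid = q$grid, values = qv * sqrt(gdot),
                 origin_value = q$origin_value),
            class = "srvf")
}
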