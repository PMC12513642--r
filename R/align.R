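#' Pairwise elastic alignment of two SRVFs
#'
#' Finds the warp \eqn{\gamma_2} minimizing
#' \eqn{\|q_1 - (q_2 \circ \gamma)\sqrt{\dot\gamma}\|^2} by dynamic
#' programming over monotone lattice paths with local slopes restricted to
#' \eqn{\{p/q : 1 \le p, q \le 3\}}. Ties between equal-cost paths are
#' broken toward the diagonal, so among minimizers the least-warping one is
#' returned and the output is deterministic.
#'
#' @param q1,q2 `"srvf"` objects on grids of the same length; `q2` is
#'   aligned to `q1`.
#' @param beta2 optionally, the trajectory whose SRVF is `q2`; when given,
#'   the aligned curve \eqn{\beta_2 \circ \gamma_2} is returned as a
#'   trajectory, otherwise it is reconstructed from the warped SRVF.
#' @return an object of class `"alignment"`: list with `warp` (a
#'   [warp_fn()]), `distance` (the attained amplitude distance), `aligned_srvf`,
#'   `aligned_curve` and `cost` (the raw lattice cost).
#' @export
pairwise_align <- function(q1, q2, beta2 = NULL) {
  stopifnot(inherits(q1, "srvf"), inherits(q2, "srvf"))
  n <- length(q1$grid)
  if (length(q2$grid) != n)
    stop("SRVF grids must have the same length", call. = FALSE)
  dt <- q1$grid[2] - q1$grid[1]
  res <- dp_align_cpp(q1$values, q2$values, dt)
  gv <- stats::approx(q1$grid[res$path_i], q1$grid[res$path_j],
                      xout = q1$grid)$y
  gv[1] <- q1$grid[1]; gv[n] <- q1$grid[n]
  # remove the lattice's slope quantization: a short symmetric moving
  # average leaves straight segments (and the identity) untouched but
  # stops gamma-dot from zigzagging between neighbouring lattice slopes,
  # then coordinate descent moves each node to its continuous optimum
  gv <- smooth_warp_values(smooth_warp_values(gv))
  g1 <- q1$grid[1]
  gv_idx <- (gv - g1) / dt
  gv_idx <- refine_warp_cpp(q1$values, q2$values, gv_idx, dt)
  gv <- g1 + gv_idx * dt
  gv[1] <- q1$grid[1]; gv[n] <- q1$grid[n]
  gamma <- warp_fn(enforce_increasing(gv, q1$grid), q1$grid)
  qa <- warp_srvf(q2, gamma)
  aligned <- if (is.null(beta2)) from_srvf(qa) else warp_trajectory(beta2, gamma)
  dist <- l2_norm(q1$values - qa$values, q1$grid)
  structure(list(warp = gamma, distance = dist, aligned_srvf = qa,
                 aligned_curve = aligned, cost = res$cost),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> amplitude distance %.4g, max |gamma(t) - t| = %.4g\n",
              x$distance, max(abs(x$warp$values - x$warp$grid))))
  invisible(x)
}

#' Amplitude (elastic) distance between two trajectories
#'
#' \eqn{d_a(\beta_1, \beta_2) = \inf_\gamma
#' \|q_1 - (q_2 \circ \gamma)\sqrt{\dot\gamma}\|}: the residual L2 misfit of
#' the SRVFs after optimal time warping. The distance compares the shapes of
#' the two movements and is (up to discretization) unchanged by arbitrary
#' time warpings of either input, so it is blind to the rate at which an
#' activity was performed. It is computed asymmetrically (curve 2 is warped
#' onto curve 1); symmetry holds only approximately on a finite grid.
#'
#' @param beta1,beta2 [trajectory()] objects on grids of the same length.
#' @return nonnegative scalar.
#' @export
amplitude_distance <- function(beta1, beta2) {
  stopifnot(inherits(beta1, "trajectory"), inherits(beta2, "trajectory"))
  pairwise_align(to_srvf(beta1), to_srvf(beta2), beta2 = beta2)$distance
}

# symmetric moving average (window 5, shrinking near the ends); exact on
# linear sequences, monotone-preserving on monotone input
smooth_warp_values <- function(v) {
  n <- length(v)
  if (n < 7L) return(v)
  out <- v
  out[3:(n - 2)] <- (v[1:(n - 4)] + v[2:(n - 3)] + v[3:(n - 2)] +
                       v[4:(n - 1)] + v[5:n]) / 5
  out[2] <- (v[1] + v[2] + v[3]) / 3
  out[n - 1] <- (v[n - 2] + v[n - 1] + v[n]) / 3
  out
}

#' Exhaustive alignment cost over all admissible lattice paths
#'
#' Enumerates every slope-constrained monotone lattice path (the same edge
#' costs and slope set as [pairwise_align()]) and returns the minimum cost.
#' This brute-force search is exponential in the grid length and is limited
#' to small grids; it exists to validate the dynamic-programming solver.
#'
#' @param q1,q2 `"srvf"` objects on a common grid of at most 24 points.
#' @return the minimal lattice cost (squared-misfit scale).
#' @export
brute_force_align_cost <- function(q1, q2) {
  stopifnot(inherits(q1, "srvf"), inherits(q2, "srvf"))
  dt <- q1$grid[2] - q1$grid[1]
  brute_align_cost_cpp(q1$values, q2$values, dt)
}
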