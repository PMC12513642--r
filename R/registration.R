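#' Karcher mean and phase-amplitude separation of a set of trajectories
#'
#' Computes the elastic (Karcher/Frechet) mean shape
#' \deqn{\hat\mu = \arg\min_q \sum_i \min_{\gamma_i}
#'       \|q - (q_i \circ \gamma_i)\sqrt{\dot\gamma_i}\|^2}
#' by alternating (1) elastic alignment of every SRVF to the current mean
#' ([pairwise_align()]) and (2) replacement of the mean by the
#' cross-sectional average of the aligned SRVFs, stopping when the relative
#' L2 change of the mean drops below `tol` or after `max_iter` sweeps. The
#' mean is initialized at the input SRVF closest in L2 to the raw
#' cross-sectional SRVF average, which is deterministic and robust to the
#' warps present in the inputs.
#'
#' Each curve is thereby decomposed into its phase \eqn{\gamma_i^*} (timing)
#' and its amplitude \eqn{\tilde\beta_i} (shape), with
#' \eqn{\beta_i = \tilde\beta_i \circ \gamma_i^*}. When `center_phase` is
#' `TRUE` (the default) the phases are re-centred after convergence so their
#' pointwise mean is the identity, and the mean shape is re-warped
#' accordingly; the decomposition identity is preserved by construction.
#'
#' @param curves list of [trajectory()] objects on a common grid (>= 2).
#' @param tol relative L2 change of the mean at which iteration stops
#'   (default 5e-3; the re-alignment step has a small discretization jitter,
#'   so much tighter tolerances are never reached).
#' @param max_iter maximum number of alignment sweeps (default 20). If the
#'   tolerance is not reached the result is returned with
#'   `converged = FALSE` and a warning; no error is raised.
#' @param center_phase re-centre phases so their pointwise mean is identity
#'   (default `TRUE`).
#' @return an object of class `"separation"`: list with `mean_srvf`,
#'   `mean_trajectory`, `phases` (list of [warp_fn()], the \eqn{\gamma_i^*}
#'   such that amplitude composed with phase reproduces the input),
#'   `amplitudes` (list of aligned trajectories \eqn{\tilde\beta_i}),
#'   `aligned_srvfs`, `distances` (amplitude distance of each curve to the
#'   mean), `iterations`, `converged`, `tol`.
#' @export
karcher_mean <- function(curves, tol = 5e-3, max_iter = 20L,
                         center_phase = TRUE) {
  stopifnot(is.list(curves), length(curves) >= 2L)
  lapply(curves, function(b) stopifnot(inherits(b, "trajectory")))
  grid <- curves[[1]]$grid
  n <- length(grid)
  for (b in curves) if (length(b$grid) != n)
    stop("all curves must share a common grid", call. = FALSE)

  qs <- lapply(curves, to_srvf)
  qmat <- vapply(qs, `[[`, numeric(n), "values")
  qbar <- rowMeans(qmat)
  # init: input SRVF closest to the cross-sectional average
  d0 <- apply(qmat, 2, function(col) l2_norm(col - qbar, grid))
  mu <- qmat[, which.min(d0)]

  iterations <- 0L
  converged <- FALSE
  warps <- NULL
  aligned <- qmat
  mu_srvf <- structure(list(grid = grid, values = mu,
                            origin_value = mean(vapply(curves, function(b) b$values[1], 0))),
                       class = "srvf")
  for (it in seq_len(max_iter)) {
    iterations <- it
    res <- lapply(qs, function(q) pairwise_align(mu_srvf, q))
    aligned <- vapply(res, function(r) r$aligned_srvf$values, numeric(n))
    warps <- lapply(res, `[[`, "warp")
    mu_new <- rowMeans(aligned)
    change <- l2_norm(mu_new - mu_srvf$values, grid) /
      max(l2_norm(mu_srvf$values, grid), .Machine$double.eps)
    mu_srvf$values <- mu_new
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("Karcher mean did not reach tol %.2g in %d iterations",
                    tol, max_iter))

  # phases: inverses of the aligning warps, so amplitude o phase == input
  phases <- lapply(warps, invert_warp)

  if (center_phase) {
    # re-centring by the mean phase is only first-order exact (composition
    # is nonlinear), so iterate until the phases average to the identity;
    # the correction is accumulated and applied to each warp once, and the
    # curves are re-warped from the originals, so interpolation error does
    # not compound across the iteration
    gcum <- NULL
    for (cc in 1:5) {
      gbar_v <- rowMeans(vapply(phases, `[[`, numeric(n), "values"))
      if (max(abs(gbar_v - grid)) < 1e-4 * (grid[n] - grid[1])) break
      gbar_v[1] <- grid[1]; gbar_v[n] <- grid[n]
      gbar <- warp_fn(enforce_increasing(gbar_v, grid), grid)
      gbar_inv <- invert_warp(gbar)
      phases <- lapply(phases, function(g) compose_warps(gbar_inv, g))
      gcum <- if (is.null(gcum)) gbar else compose_warps(gcum, gbar)
    }
    if (!is.null(gcum)) {
      # composition resamples the warps; one light smoothing pass removes
      # the resulting slope jitter before the final re-warp
      warps <- lapply(warps, function(w) {
        v <- smooth_warp_values(compose_warps(w, gcum)$values)
        v[1] <- grid[1]; v[n] <- grid[n]
        warp_fn(enforce_increasing(v, grid), grid)
      })
      phases <- lapply(warps, invert_warp)
    }
  }

  amplitudes <- Map(function(b, g) warp_trajectory(b, g), curves, warps)
  aligned_srvfs <- Map(function(q, g) warp_srvf(q, g), qs, warps)
  mu_v <- rowMeans(vapply(aligned_srvfs, `[[`, numeric(n), "values"))
  mu_srvf <- structure(list(grid = grid, values = mu_v,
                            origin_value = mu_srvf$origin_value),
                       class = "srvf")

  dists <- vapply(aligned_srvfs, function(q)
    l2_norm(q$values - mu_srvf$values, grid), 0)
  mean_traj <- from_srvf(mu_srvf)

  structure(list(mean_srvf = mu_srvf, mean_trajectory = mean_traj,
                 phases = phases, amplitudes = amplitudes,
                 aligned_srvfs = aligned_srvfs, distances = dists,
                 iterations = iterations, converged = converged, tol = tol,
                 curves = curves),
            class = "separation")
}

#' Separate phases and amplitudes of a set of trajectories
#'
#' Convenience wrapper around [karcher_mean()]: the amplitudes are the
#' aligned curves, the phases the warps that restore the original timing
#' (so `amplitude o phase` reproduces each input curve).
#'
#' @inheritParams karcher_mean
#' @return a `"separation"` object; see [karcher_mean()].
#' @export
separate_phase_amplitude <- function(curves, tol = 5e-3, max_iter = 20L,
                                     center_phase = TRUE) {
  karcher_mean(curves, tol = tol, max_iter = max_iter,
               center_phase = center_phase)
}

#' @export
print.separation <- function(x, ...) {
  cat(sprintf(paste0("<separation> %d curves, %d iterations (%s), ",
                     "mean amplitude distance to mean shape %.4g\n"),
              length(x$phases), x$iterations,
              if (x$converged) "converged" else "not converged",
              mean(x$distances)))
  invisible(x)
}

#' @export
plot.separation <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3)); on.exit(graphics::par(op))
  g <- x$mean_srvf$grid
  vals <- vapply(x$curves, `[[`, numeric(length(g)), "values")
  graphics::matplot(g, vals, type = "l", lty = 1, col = "grey60",
                    xlab = "time", ylab = "value", main = "original")
  ph <- vapply(x$phases, `[[`, numeric(length(g)), "values")
  graphics::matplot(g, ph, type = "l", lty = 1, col = "grey40",
                    xlab = "time", ylab = "warped time", main = "phases")
  am <- vapply(x$amplitudes, `[[`, numeric(length(g)), "values")
  graphics::matplot(g, am, type = "l", lty = 1, col = "grey60",
                    xlab = "time", ylab = "value", main = "amplitudes + mean")
  graphics::lines(g, x$mean_trajectory$values, col = "blue", lwd = 2)
  invisible(x)
}

#' Align a set of trajectories to a fixed reference shape
#'
#' Aligns each curve independently to a fixed reference SRVF (for example,
#' the mean shape of the healthy cohort) rather than to the set's own mean.
#' The returned distances summarize how far each movement deviates from the
#' reference shape after its timing has been matched: phase can be absorbed,
#' amplitude differences cannot.
#'
#' @param curves list of [trajectory()] objects on the reference grid.
#' @param reference an `"srvf"` object (e.g. `sep$mean_srvf`).
#' @return list of `"alignment"` objects (one per curve).
#' @export
align_to_reference <- function(curves, reference) {
  stopifnot(is.list(curves), inherits(reference, "srvf"))
  lapply(curves, function(b) {
    stopifnot(inherits(b, "trajectory"))
    pairwise_align(reference, to_srvf(b), beta2 = b)
  })
}

#' Cross-sectional (Euclidean) mean of a set of trajectories
#'
#' Pointwise average of the sampled values, with no time alignment. Used
#' only as the contrast baseline: when curves contain phase variability the
#' Euclidean mean smears and distorts the common shape, which the elastic
#' mean of [karcher_mean()] does not.
#'
#' @param curves list of [trajectory()] objects on a common grid.
#' @return a [trajectory()].
#' @export
euclidean_mean <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  n <- length(curves[[1]]$grid)
  vals <- vapply(curves, `[[`, numeric(n), "values")
  trajectory(rowMeans(vals), curves[[1]]$grid)
}

#' Write a separation result to a directory
#'
#' Serializes a `"separation"` object as plain text: the mean curve and mean
#' SRVF (`mean.csv`), the phases (`phases.csv`, wide, one column per curve),
#' the amplitudes (`amplitudes.csv`, wide) and JSON metadata
#' (`separation.json`: tolerance, iterations, convergence flag, distances).
#'
#' @param x a `"separation"` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_separation <- function(x, dir) {
  stopifnot(inherits(x, "separation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- x$mean_srvf$grid
  utils::write.csv(data.frame(t = g, mean = x$mean_trajectory$values,
                              mean_srvf = x$mean_srvf$values),
                   file.path(dir, "mean.csv"), row.names = FALSE)
  ph <- as.data.frame(vapply(x$phases, `[[`, numeric(length(g)), "values"))
  names(ph) <- paste0("curve", seq_along(x$phases))
  utils::write.csv(cbind(t = g, ph), file.path(dir, "phases.csv"),
                   row.names = FALSE)
  am <- as.data.frame(vapply(x$amplitudes, `[[`, numeric(length(g)), "values"))
  names(am) <- paste0("curve", seq_along(x$amplitudes))
  utils::write.csv(cbind(t = g, am), file.path(dir, "amplitudes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(tol = x$tol, iterations = x$iterations,
                            converged = x$converged,
                            distances = x$distances),
                       file.path(dir, "separation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
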