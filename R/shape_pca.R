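#' Vertical (shape) PCA of aligned SRVFs
#'
#' Functional PCA in SRVF space after phase removal. The aligned SRVFs are
#' mean-centred, the covariance (1/(n-1) normalization) is decomposed by
#' SVD, and the leading directions are kept. Because the phase has already
#' been separated, the retained directions describe amplitude (shape)
#' variability only; projections on them are the Vertical Principal
#' Components (VPCs). In wrist-gyroscope data VPC1 typically encodes the
#' overall speed/scale of the movement and VPC2 its asymmetry.
#'
#' Components are orthonormal under the discrete L2 inner product (the same
#' (T/J)-weighted sum used by [l2_norm()]), so scores approximate the
#' integral inner products \eqn{c_{ik} = \langle q_i - \mu, U_k\rangle}. The
#' sign of each component is fixed at fit time so that its value at the grid
#' point of maximal raw variance is nonnegative; sign alignment across
#' repeated fits is handled separately by [repeated_shape_pca()].
#'
#' @param aligned a `"separation"` object from [karcher_mean()], or a list
#'   of aligned `"srvf"` objects on a common grid (>= 3).
#' @param n_retained number of components to retain (default 3; truncated
#'   with a warning if it exceeds `n - 1`).
#' @return an object of class `"shape_pca"`: list with `mean_srvf`,
#'   `components` (grid-length x k matrix), `singular_values` (full
#'   nonincreasing spectrum of the covariance), `sdev`,
#'   `variance_fractions`, `scores` (n x k matrix of VPC scores of the
#'   training curves), `n_retained`, `grid`.
#' @export
fit_shape_pca <- function(aligned, n_retained = 3L) {
  if (inherits(aligned, "separation")) aligned <- aligned$aligned_srvfs
  stopifnot(is.list(aligned), length(aligned) >= 3L)
  lapply(aligned, function(q) stopifnot(inherits(q, "srvf")))
  grid <- aligned[[1]]$grid
  N <- length(grid)
  n <- length(aligned)
  w <- (grid[N] - grid[1]) / N  # quadrature weight matching l2_norm()

  Q <- t(vapply(aligned, `[[`, numeric(N), "values"))  # n x N
  mu <- colMeans(Q)
  Qc <- sweep(Q, 2L, mu)
  if (n_retained > n - 1L) {
    warning(sprintf("n_retained reduced from %d to %d (only %d curves)",
                    n_retained, n - 1L, n))
    n_retained <- n - 1L
  }
  B <- Qc * sqrt(w)
  s <- svd(B / sqrt(n - 1))
  lambda <- s$d^2                       # eigenvalues of the covariance
  k_max <- min(n - 1L, N)
  lambda <- lambda[seq_len(k_max)]
  V <- s$v[, seq_len(k_max), drop = FALSE]

  # sign convention: component nonnegative at the point of maximal variance
  j_star <- which.max(apply(Qc, 2L, stats::var))
  flip <- ifelse(V[j_star, ] < 0, -1, 1)
  V <- sweep(V, 2L, flip, `*`)

  comps <- V / sqrt(w)                  # functional components U_k(t)
  scores_full <- B %*% V                # <q_i - mu, U_k> by quadrature
  k <- n_retained
  mean_srvf <- structure(list(grid = grid, values = mu,
                              origin_value = mean(vapply(aligned, `[[`, 0,
                                                         "origin_value"))),
                         class = "srvf")
  scores <- scores_full[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("VPC", seq_len(k))
  structure(list(mean_srvf = mean_srvf,
                 components = comps[, seq_len(k), drop = FALSE],
                 components_full = comps,
                 singular_values = lambda,
                 sdev = sqrt(pmax(lambda, 0)),
                 variance_fractions = lambda / sum(lambda),
                 scores = scores, n_retained = k, grid = grid, weight = w,
                 n_curves = n),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  vf <- x$variance_fractions[seq_len(x$n_retained)]
  cat(sprintf("<shape_pca> %d curves, %d retained components\n",
              x$n_curves, x$n_retained))
  cat("  variance explained:",
      paste(sprintf("VPC%d %.1f%%", seq_along(vf), 100 * vf), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.shape_pca <- function(object, ...) {
  k <- length(object$singular_values)
  out <- data.frame(component = seq_len(k),
                    variance = object$singular_values,
                    fraction = object$variance_fractions,
                    cumulative = cumsum(object$variance_fractions))
  attr(out, "n_retained") <- object$n_retained
  out
}

#' Project an aligned SRVF on the shape-PCA directions
#'
#' Returns the VPC scores \eqn{c_k = \langle q - \mu, U_k\rangle} of a
#' (phase-separated) SRVF; the mean shape projects to zero on every
#' component.
#'
#' @param q an `"srvf"` object on the model grid.
#' @param model a `"shape_pca"` object.
#' @return named numeric vector of length `n_retained`.
#' @export
project_srvf <- function(q, model) {
  stopifnot(inherits(q, "srvf"), inherits(model, "shape_pca"))
  if (length(q$grid) != length(model$grid))
    stop("SRVF is not on the model grid", call. = FALSE)
  ctr <- q$values - model$mean_srvf$values
  sc <- model$weight * drop(crossprod(model$components, ctr))
  names(sc) <- paste0("VPC", seq_along(sc))
  sc
}

#' @param object a `"shape_pca"` model.
#' @param newdata an `"srvf"` or a list of them.
#' @param ... unused.
#' @rdname project_srvf
#' @export
predict.shape_pca <- function(object, newdata, ...) {
  if (inherits(newdata, "srvf")) return(project_srvf(newdata, object))
  t(vapply(newdata, project_srvf, numeric(object$n_retained), model = object))
}

#' Traverse a principal mode of shape variation
#'
#' Reconstructs the trajectories \eqn{F^{-1}(\mu + s\,\sigma_k U_k)} for the
#' requested multiples `s` of the component's standard deviation
#' \eqn{\sigma_k = \sqrt{\lambda_k}}, where \eqn{F} is the SRVF map. Plotting
#' these curves against the mean is how modes are labelled: a speed mode
#' scales/widens the whole movement, an asymmetry mode depresses the peak
#' while leaving the trough intact (see [asymmetry_statistic()]).
#'
#' @param model a `"shape_pca"` object.
#' @param k component index (1-based, at most `n_retained`).
#' @param sigmas multiples of the component standard deviation
#'   (default `c(-2, -1, 0, 1, 2)`).
#' @return list of [trajectory()] objects, one per entry of `sigmas`.
#' @export
mode_traversal <- function(model, k, sigmas = c(-2, -1, 0, 1, 2)) {
  stopifnot(inherits(model, "shape_pca"))
  if (!(k >= 1L && k <= model$n_retained))
    stop(sprintf("component index %s outside 1..%d", k, model$n_retained),
         call. = FALSE)
  lapply(sigmas, function(s) {
    q <- model$mean_srvf
    q$values <- q$values + s * model$sdev[k] * model$components[, k]
    from_srvf(q)
  })
}

#' @export
plot.shape_pca <- function(x, k = 1L, sigmas = c(-1, 0, 1), ...) {
  tr <- mode_traversal(x, k, sigmas)
  vals <- vapply(tr, `[[`, numeric(length(x$grid)), "values")
  graphics::matplot(x$grid, vals, type = "l", lty = 1,
                    col = grDevices::hcl.colors(length(sigmas), "Zissou 1"),
                    xlab = "time", ylab = "angular velocity",
                    main = sprintf("VPC%d traversal", k), ...)
  graphics::legend("topright", legend = sprintf("%+g sd", sigmas), lty = 1,
                   col = grDevices::hcl.colors(length(sigmas), "Zissou 1"),
                   bty = "n")
  invisible(x)
}

#' Peak-trough asymmetry of a movement curve
#'
#' Quantifies asymmetry between the upward and downward phase of a movement
#' as \eqn{(|peak| - |trough|) / (|peak| + |trough|)}, where peak is the
#' maximal positive excursion and trough the maximal negative excursion of
#' the angular-velocity curve. The statistic is 0 for an odd-symmetric
#' movement, positive when the peak dominates, negative when the trough
#' dominates (e.g. a slowed upward phase with a gravity-assisted downward
#' phase). Used to label shape-PCA modes objectively.
#'
#' @param curve a [trajectory()].
#' @return scalar in `[-1, 1]`; 0 (with a warning) for a flat curve.
#' @export
asymmetry_statistic <- function(curve) {
  stopifnot(inherits(curve, "trajectory"))
  pk <- max(c(curve$values, 0))
  tr <- -min(c(curve$values, 0))
  if (pk + tr <= .Machine$double.eps) {
    warning("flat curve: asymmetry statistic undefined, returning 0")
    return(0)
  }
  (pk - tr) / (pk + tr)
}

#' Integrated mirror asymmetry of a curve
#'
#' \eqn{\int |\beta(t) - \beta(T - t)|\,dt}: zero iff the curve is symmetric
#' about the midpoint of its domain. Used to compare how faithfully the
#' elastic mean and the Euclidean mean preserve a symmetric template shape.
#'
#' @param curve a [trajectory()].
#' @return nonnegative scalar.
#' @export
mirror_asymmetry <- function(curve) {
  stopifnot(inherits(curve, "trajectory"))
  v <- curve$values
  w <- (curve$grid[length(curve$grid)] - curve$grid[1]) / length(v)
  sum(abs(v - rev(v))) * w
}

#' Write a shape-PCA model to a directory
#'
#' Plain-text serialization: mean SRVF and components (`components.csv`),
#' spectrum (`spectrum.csv`), training scores (`scores.csv`) and JSON
#' metadata (`shape_pca.json`).
#'
#' @param x a `"shape_pca"` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_shape_pca <- function(x, dir) {
  stopifnot(inherits(x, "shape_pca"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comp <- as.data.frame(x$components)
  names(comp) <- paste0("VPC", seq_len(ncol(comp)))
  utils::write.csv(cbind(t = x$grid, mean_srvf = x$mean_srvf$values, comp),
                   file.path(dir, "components.csv"), row.names = FALSE)
  utils::write.csv(data.frame(component = seq_along(x$singular_values),
                              variance = x$singular_values,
                              fraction = x$variance_fractions),
                   file.path(dir, "spectrum.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(x$scores), file.path(dir, "scores.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(n_curves = x$n_curves, n_retained = x$n_retained,
                            weight = x$weight),
                       file.path(dir, "shape_pca.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
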