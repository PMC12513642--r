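#' Two-block partial least squares in canonical mode
#'
#' Fits canonical-mode PLS between a block of wearable features `X`
#' (typically the VPC scores `VPC1_curl`, `VPC2_curl`, `VPC1_knock`,
#' `VPC2_knock`) and a block of clinical variables `Y` (age, average
#' echogenicity, normalized elbow torque, Brooke score). Both blocks are
#' standardized; per component the weight pair is the leading singular-vector
#' pair of the cross-covariance matrix, and both blocks are deflated
#' symmetrically on their own scores (canonical mode). The first component's
#' X-side weights define the motor-function index.
#'
#' Rows with missing values are dropped (complete-case), constant columns
#' are dropped with a warning, and `n_components` is truncated to the
#' smaller block dimension. Weight signs are fixed so the largest-magnitude
#' X weight of each component is positive; flipping both weight vectors of a
#' component leaves all correlations unchanged.
#'
#' @param X numeric matrix or data frame of features (rows = subjects).
#' @param Y numeric matrix or data frame of clinical variables.
#' @param n_components number of latent component pairs (default 1).
#' @return an object of class `"pls_fit"`: weights (`x_weights`,
#'   `y_weights`), loadings, rotations (for scoring new data), block
#'   centring/scaling, training scores, and `cor_train` (the training
#'   canonical correlation per component).
#' @export
fit_pls <- function(X, Y, n_components = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  cc <- stats::complete.cases(X) & stats::complete.cases(Y)
  n_dropped <- sum(!cc)
  X <- X[cc, , drop = FALSE]; Y <- Y[cc, , drop = FALSE]
  if (nrow(X) < 5L) stop("need at least 5 complete cases", call. = FALSE)

  drop_const <- function(M, label) {
    sds <- apply(M, 2L, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("dropping constant %s column(s): %s", label,
                      paste(colnames(M)[sds == 0], collapse = ", ")))
      M <- M[, sds > 0, drop = FALSE]
    }
    M
  }
  X <- drop_const(X, "X"); Y <- drop_const(Y, "Y")
  k_max <- min(ncol(X), ncol(Y))
  if (n_components > k_max) {
    warning(sprintf("n_components truncated from %d to %d",
                    n_components, k_max))
    n_components <- k_max
  }

  x_center <- colMeans(X); y_center <- colMeans(Y)
  x_scale <- apply(X, 2L, stats::sd); y_scale <- apply(Y, 2L, stats::sd)
  Xd <- scale(X, x_center, x_scale); Yd <- scale(Y, y_center, y_scale)
  Xs <- Xd; Ys <- Yd
  p <- ncol(X); q <- ncol(Y); k <- n_components
  W <- matrix(0, p, k, dimnames = list(colnames(X), NULL))
  C <- matrix(0, q, k, dimnames = list(colnames(Y), NULL))
  P <- matrix(0, p, k); Qm <- matrix(0, q, k)
  TT <- matrix(0, nrow(X), k); U <- matrix(0, nrow(X), k)
  cor_train <- numeric(k)
  for (h in seq_len(k)) {
    M <- crossprod(Xd, Yd)
    sv <- svd(M, nu = 1L, nv = 1L)
    w <- sv$u[, 1L]; cvec <- sv$v[, 1L]
    i_star <- which.max(abs(w))
    if (w[i_star] < 0) { w <- -w; cvec <- -cvec }
    xi <- drop(Xd %*% w); om <- drop(Yd %*% cvec)
    W[, h] <- w; C[, h] <- cvec; TT[, h] <- xi; U[, h] <- om
    P[, h] <- drop(crossprod(Xd, xi)) / sum(xi^2)
    Qm[, h] <- drop(crossprod(Yd, om)) / sum(om^2)
    cor_train[h] <- stats::cor(xi, om)
    Xd <- Xd - tcrossprod(xi, P[, h])
    Yd <- Yd - tcrossprod(om, Qm[, h])
  }
  x_rotations <- W %*% solve(crossprod(P, W))
  y_rotations <- C %*% solve(crossprod(Qm, C))
  structure(list(x_weights = W, y_weights = C,
                 x_loadings = P, y_loadings = Qm,
                 x_rotations = x_rotations, y_rotations = y_rotations,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 x_scores = TT, y_scores = U,
                 cor_train = cor_train, n_components = k,
                 n = nrow(X), n_dropped = n_dropped),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit> %d component(s), n = %d\n", x$n_components, x$n))
  cat("  training canonical correlation:",
      paste(sprintf("%.3f", x$cor_train), collapse = ", "), "\n")
  cat("  index weights (component 1):\n")
  print(round(x$x_weights[, 1L], 3))
  invisible(x)
}

#' @param object a `"pls_fit"`.
#' @param ... unused.
#' @rdname fit_pls
#' @export
coef.pls_fit <- function(object, ...) object$x_weights[, 1L]

#' Score new data with a fitted PLS model
#'
#' Standardizes `newX` (and `newY` if given) with the training centring and
#' scaling and applies the model rotations, yielding per-component latent
#' scores; the per-component Pearson correlation between paired scores on
#' held-out subjects is the test canonical correlation used throughout the
#' bootstrap.
#'
#' @param object a `"pls_fit"`.
#' @param newX,newY matrices with the training columns.
#' @param ... unused.
#' @return list with `x_scores` and (if `newY` given) `y_scores`.
#' @export
predict.pls_fit <- function(object, newX, newY = NULL, ...) {
  newX <- as.matrix(newX)[, names(object$x_center), drop = FALSE]
  xs <- scale(newX, object$x_center, object$x_scale) %*% object$x_rotations
  out <- list(x_scores = xs)
  if (!is.null(newY)) {
    newY <- as.matrix(newY)[, names(object$y_center), drop = FALSE]
    out$y_scores <- scale(newY, object$y_center, object$y_scale) %*%
      object$y_rotations
  }
  out
}
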