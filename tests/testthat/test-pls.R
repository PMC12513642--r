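test_that("a noiseless linear map gives a perfect first canonical pair", {
  set.seed(51)
  X <- matrix(rnorm(200 * 4), 200, 4)
  colnames(X) <- paste0("x", 1:4)
  # full-rank signed, scaled permutation: Y spans the same standardized block
  A <- diag(c(2, -1, 0.5, 3))[, c(2, 1, 4, 3)]
  Y <- X %*% A
  f <- fit_pls(X, Y, n_components = 2L)
  expect_equal(f$cor_train[1], 1, tolerance = 1e-6)
})

test_that("weights are unit norm and sign conventions hold", {
  sf <- simulate_features(100, snr = 3, seed = 52)
  f <- fit_pls(sf$X, sf$Y, n_components = 2L)
  expect_equal(colSums(f$x_weights^2), rep(1, 2), tolerance = 1e-10)
  # flipping both weight vectors leaves the correlation unchanged
  xi <- scale(sf$X) %*% (-f$x_weights[, 1])
  om <- scale(sf$Y) %*% (-f$y_weights[, 1])
  expect_equal(stats::cor(xi, om)[1, 1], f$cor_train[1], tolerance = 1e-10)
  # largest-magnitude X weight is positive
  expect_gt(f$x_weights[which.max(abs(f$x_weights[, 1])), 1], 0)
})

test_that("generating weights are recovered at n = 200, SNR 3:1", {
  sf <- simulate_features(200, snr = 3, seed = 53)
  f <- fit_pls(sf$X, sf$Y)
  cosine <- abs(sum(coef(f) * sf$weights)) / sqrt(sum(coef(f)^2))
  expect_gt(cosine, 0.9)
})

test_that("degenerate inputs are handled by dropping and truncating", {
  set.seed(54)
  X <- cbind(matrix(rnorm(60), 20, 3), const = 1)
  Y <- matrix(rnorm(40), 20, 2)
  expect_warning(f <- fit_pls(X, Y), "constant")
  expect_equal(nrow(f$x_weights), 3L)
  expect_warning(f2 <- fit_pls(X[, 1:3], Y, n_components = 5L), "truncated")
  expect_equal(f2$n_components, 2L)
  expect_error(fit_pls(X[1:4, ], Y[1:4, ]), "at least 5")
})

test_that("predict scores held-out data consistently with training scores", {
  sf <- simulate_features(120, snr = 3, seed = 55)
  f <- fit_pls(sf$X, sf$Y, n_components = 2L)
  sc <- predict(f, sf$X, sf$Y)
  expect_equal(sc$x_scores, f$x_scores, ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(sc$y_scores, f$y_scores, ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("canonical-mode PLS agrees with an independent implementation", {
  skip_if_not_installed("mixOmics")
  sf <- simulate_features(80, snr = 3, seed = 56)
  f <- fit_pls(sf$X, sf$Y, n_components = 2L)
  ref <- mixOmics::pls(sf$X, sf$Y, ncomp = 2, mode = "canonical",
                       scale = TRUE)
  for (h in 1:2) {
    w_ref <- ref$loadings$X[, h]
    w_ref <- w_ref / sqrt(sum(w_ref^2))
    expect_gt(abs(sum(f$x_weights[, h] * w_ref)), 0.999)
  }
})
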