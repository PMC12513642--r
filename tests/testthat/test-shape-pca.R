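# helper: build srvf objects directly from value vectors on the unit grid
srvf_from <- function(v, g = unit_grid(length(v)), origin = 0) {
  structure(list(grid = g, values = v, origin_value = origin), class = "srvf")
}

test_that("a rank-1 ensemble yields exactly one nonzero singular value", {
  g <- unit_grid(100)
  mu <- sin(2 * pi * g)
  v <- cos(pi * g)
  qs <- lapply(c(-2, -1, 1, 2), function(c) srvf_from(mu + c * v, g))
  m <- fit_shape_pca(qs, n_retained = 3L)
  expect_gt(m$singular_values[1], 0)
  expect_lt(m$singular_values[2] / m$singular_values[1], 1e-12)
  # component 1 proportional to v (unit L2 norm, sign fixed by convention)
  vn <- v / l2_norm(v, g)
  expect_lt(min(l2_norm(m$components[, 1] - vn, g),
                l2_norm(m$components[, 1] + vn, g)), 1e-6)
})

test_that("variance fractions sum to one and the spectrum is sorted", {
  set.seed(12)
  qs <- lapply(1:8, function(i) to_srvf(random_smooth_curve(100L)))
  m <- fit_shape_pca(qs, n_retained = 3L)
  expect_equal(sum(m$variance_fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(m$singular_values) <= 1e-12))
})

test_that("components are orthonormal under the discrete L2 inner product", {
  set.seed(18)
  qs <- lapply(1:10, function(i) to_srvf(random_smooth_curve(150L)))
  m <- fit_shape_pca(qs, n_retained = 5L)
  w <- m$weight
  G <- w * crossprod(m$components)
  expect_lt(max(abs(G - diag(5))), 1e-6)
})

test_that("scores match a direct quadrature oracle", {
  set.seed(30)
  qs <- lapply(1:7, function(i) to_srvf(random_smooth_curve(120L)))
  m <- fit_shape_pca(qs, n_retained = 3L)
  w <- m$weight
  for (i in seq_along(qs)) {
    ctr <- qs[[i]]$values - m$mean_srvf$values
    oracle <- vapply(1:3, function(k) w * sum(ctr * m$components[, k]), 0)
    expect_equal(unname(m$scores[i, ]), oracle, tolerance = 1e-10)
  }
})

test_that("projection centres at the mean and respects the traversal scale", {
  set.seed(31)
  qs <- lapply(1:8, function(i) to_srvf(random_smooth_curve(100L)))
  m <- fit_shape_pca(qs, n_retained = 3L)
  expect_equal(unname(project_srvf(m$mean_srvf, m)), rep(0, 3),
               tolerance = 1e-10)
  q1 <- m$mean_srvf
  q1$values <- q1$values + m$sdev[1] * m$components[, 1]
  sc <- project_srvf(q1, m)
  expect_equal(unname(sc), c(m$sdev[1], 0, 0), tolerance = 1e-8)
})

test_that("full-rank reconstruction is exact and error is monotone in rank", {
  set.seed(32)
  qs <- lapply(1:6, function(i) to_srvf(random_smooth_curve(80L)))
  g <- unit_grid(80)
  m <- fit_shape_pca(qs, n_retained = 5L)
  errs <- vapply(1:5, function(k) {
    mean(vapply(qs, function(q) {
      ctr <- q$values - m$mean_srvf$values
      sc <- m$weight * drop(crossprod(m$components[, 1:k, drop = FALSE], ctr))
      rec <- m$mean_srvf$values +
        drop(m$components[, 1:k, drop = FALSE] %*% sc)
      l2_norm(q$values - rec, g)
    }, 0))
  }, 0)
  expect_true(all(diff(errs) <= 1e-10))
  expect_lt(errs[5], 1e-6)  # rank = n - 1 completes the span
})

test_that("n_retained is truncated with a warning when too large", {
  qs <- lapply(1:4, function(i) to_srvf(random_smooth_curve(60L)))
  expect_warning(m <- fit_shape_pca(qs, n_retained = 10L), "reduced")
  expect_equal(m$n_retained, 3L)
})

test_that("mode traversal reproduces the mean at s = 0 and mirrors at +/- s", {
  set.seed(33)
  qs <- lapply(1:8, function(i) to_srvf(random_smooth_curve(100L)))
  m <- fit_shape_pca(qs, n_retained = 2L)
  tr <- mode_traversal(m, 1, sigmas = c(-1, 0, 1))
  expect_equal(tr[[2]]$values, from_srvf(m$mean_srvf)$values, tolerance = 1e-10)
  # mu + sv and mu - sv average back to mu in SRVF space
  qp <- m$mean_srvf$values + m$sdev[1] * m$components[, 1]
  qm <- m$mean_srvf$values - m$sdev[1] * m$components[, 1]
  expect_equal((qp + qm) / 2, m$mean_srvf$values, tolerance = 1e-12)
  expect_error(mode_traversal(m, 5), "outside")
})

test_that("the speed mode traversal changes duration at half maximum", {
  # ensemble driven by a known speed latent (faster = taller and narrower)
  set.seed(34)
  speeds <- seq(0.6, 1.5, length.out = 30)
  curves <- lapply(speeds, function(s) make_template("curl", speed = s))
  # the family carries no random phase, so the SRVFs are analysed directly:
  # VPC1 then captures the joint height/duration signature of speed
  m <- fit_shape_pca(lapply(curves, to_srvf), n_retained = 2L)
  fwhm <- function(b) {
    v <- b$values
    mean(v >= max(v) / 2)  # fraction of the grid above half peak
  }
  widths <- vapply(mode_traversal(m, 1, sigmas = c(-2, -1, 0, 1, 2)), fwhm, 0)
  expect_true(all(diff(widths) > 0) || all(diff(widths) < 0))
})

test_that("the asymmetry statistic matches closed forms and the generator", {
  g <- unit_grid(100)
  expect_equal(asymmetry_statistic(trajectory(sin(2 * pi * g), g)), 0,
               tolerance = 1e-9)
  # peak twice the trough depth
  v <- ifelse(sin(2 * pi * g) > 0, 2 * sin(2 * pi * g), sin(2 * pi * g))
  expect_equal(asymmetry_statistic(trajectory(v, g)), 1 / 3, tolerance = 1e-6)
  expect_warning(z <- asymmetry_statistic(trajectory(rep(0, 100), g)), "flat")
  expect_equal(z, 0)
  # closed form from the template definition: statistic == -asymmetry
  expect_equal(asymmetry_statistic(make_template("curl", 1, 0.5)), -0.5,
               tolerance = 1e-9)
  # the statistic tracks the generating asymmetry latent across an ensemble
  set.seed(35)
  asyms <- runif(40, -0.6, 0.6)
  stats <- vapply(asyms, function(a)
    asymmetry_statistic(make_template("curl", speed = runif(1, 0.7, 1.3),
                                      asymmetry = a)), 0)
  expect_gt(abs(cor(stats, asyms)), 0.9)
})

test_that("mirror asymmetry is zero only for symmetric curves", {
  g <- unit_grid(100)
  expect_equal(mirror_asymmetry(trajectory(exp(-(g - 0.5)^2 / 0.01), g)), 0,
               tolerance = 1e-12)
  expect_gt(mirror_asymmetry(trajectory(exp(-(g - 0.4)^2 / 0.01), g)), 0.01)
})

test_that("shape PCA models serialize to plain text", {
  set.seed(36)
  qs <- lapply(1:5, function(i) to_srvf(random_smooth_curve(60L)))
  m <- fit_shape_pca(qs, n_retained = 2L)
  d <- withr::local_tempdir()
  write_shape_pca(m, d)
  comp <- utils::read.csv(file.path(d, "components.csv"))
  expect_equal(nrow(comp), 60L)
  expect_true(all(c("t", "mean_srvf", "VPC1", "VPC2") %in% names(comp)))
})
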