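test_that("the Karcher mean of identical curves is that curve", {
  b <- smooth_curve_library()[[1]]
  curves <- rep(list(b), 5)
  sep <- karcher_mean(curves)
  expect_true(sep$converged)
  expect_lte(sep$iterations, 2L)
  q <- to_srvf(b)
  expect_lt(l2_norm(sep$mean_srvf$values - q$values, b$grid) /
              l2_norm(q$values, b$grid), 1e-6)
  for (p in sep$phases)
    expect_lt(max(abs(p$values - p$grid)), 2 / 199)
})

test_that("the returned mean beats either input as a two-curve template", {
  b1 <- smooth_curve_library()[[1]]
  b2 <- smooth_curve_library()[[2]]
  sep <- karcher_mean(list(b1, b2))
  qs <- list(to_srvf(b1), to_srvf(b2))
  total_cost <- function(mu) {
    sum(vapply(qs, function(q) pairwise_align(mu, q)$distance^2, 0))
  }
  c_mean <- total_cost(sep$mean_srvf)
  expect_lte(c_mean, total_cost(qs[[1]]) + 1e-8)
  expect_lte(c_mean, total_cost(qs[[2]]) + 1e-8)
})

test_that("separation decomposes each curve into amplitude o phase", {
  be <- bump_ensemble(12, 0.7, seed = 2)
  sep <- suppressWarnings(separate_phase_amplitude(be$curves))
  g <- be$template$grid
  for (i in seq_along(be$curves)) {
    rec <- warp_trajectory(sep$amplitudes[[i]], sep$phases[[i]])
    expect_lt(l2_norm(rec$values - be$curves[[i]]$values, g) /
                l2_norm(be$curves[[i]]$values, g), 0.02)
  }
})

test_that("amplitude-only ensembles get near-identity phases", {
  be <- bump_ensemble(10, 0, seed = 4)  # no warps at all
  sep <- suppressWarnings(separate_phase_amplitude(be$curves))
  for (p in sep$phases)
    expect_lt(max(abs(p$values - p$grid)), 3 / 199)
})

test_that("warps of one template separate into a common amplitude", {
  set.seed(6)
  b <- smooth_curve_library()[[2]]
  curves <- lapply(1:8, function(i) warp_trajectory(b, make_warp(0.6)))
  sep <- suppressWarnings(separate_phase_amplitude(curves))
  nq <- l2_norm(to_srvf(b)$values, b$grid)
  for (i in 1:7) {
    d <- amplitude_distance(sep$amplitudes[[i]], sep$amplitudes[[i + 1]])
    expect_lt(d / nq, 0.05)
  }
})

test_that("separation does not increase the total misfit to the mean", {
  be <- bump_ensemble(10, 0.6, seed = 9)
  sep <- suppressWarnings(separate_phase_amplitude(be$curves))
  qs <- lapply(be$curves, to_srvf)
  g <- be$template$grid
  qbar <- rowMeans(vapply(qs, `[[`, numeric(200), "values"))
  raw <- sum(vapply(qs, function(q) l2_norm(q$values - qbar, g)^2, 0))
  aligned <- sum(sep$distances^2)
  expect_lt(aligned, raw)
})

test_that("the shape mean is stable under warping all inputs", {
  set.seed(15)
  be <- bump_ensemble(10, 0.3, seed = 15)
  sep1 <- suppressWarnings(karcher_mean(be$curves))
  warped <- lapply(be$curves, function(b) warp_trajectory(b, make_warp(0.5)))
  sep2 <- suppressWarnings(karcher_mean(warped))
  d <- amplitude_distance(sep1$mean_trajectory, sep2$mean_trajectory)
  expect_lt(d / l2_norm(sep1$mean_srvf$values, be$template$grid), 0.05)
})

test_that("alignment to a fixed reference exposes amplitude deviations", {
  set.seed(21)
  ref_curve <- make_template("curl", speed = 1, asymmetry = 0)
  ref <- to_srvf(ref_curve)
  # warps of the reference align almost perfectly
  curves <- lapply(1:5, function(i) warp_trajectory(ref_curve, make_warp(0.5)))
  res <- align_to_reference(curves, ref)
  nq <- l2_norm(ref$values, ref_curve$grid)
  for (r in res) expect_lt(r$distance / nq, 0.05)
  # the reference aligned to itself: identity warp
  self <- align_to_reference(list(ref_curve), ref)[[1]]
  expect_lt(max(abs(self$warp$values - self$warp$grid)), 2 / 199)
  # a flattened peak survives alignment: phase cannot absorb amplitude
  defect <- make_template("curl", speed = 1, asymmetry = 0.5)
  d_def <- align_to_reference(list(warp_trajectory(defect, make_warp(0.5))),
                              ref)[[1]]$distance
  d_ctrl <- max(vapply(res, `[[`, 0, "distance"))
  expect_gt(d_def, d_ctrl)
})

test_that("the Euclidean mean is the pointwise average", {
  b <- smooth_curve_library()[[1]]
  expect_trajectory_equal(euclidean_mean(rep(list(b), 4)), b, tol = 1e-12)
  g <- unit_grid(100)
  b1 <- trajectory(exp(-(g - 0.35)^2 / 0.005), g)
  b2 <- trajectory(exp(-(g - 0.65)^2 / 0.005), g)
  em <- euclidean_mean(list(b1, b2))
  expect_lt(max(em$values), max(b1$values))
  expect_lt(max(em$values), max(b2$values))
})

test_that("separation results serialize to plain text", {
  be <- bump_ensemble(5, 0.4, seed = 3)
  sep <- suppressWarnings(separate_phase_amplitude(be$curves))
  d <- withr::local_tempdir()
  write_separation(sep, d)
  expect_true(all(file.exists(file.path(d, c("mean.csv", "phases.csv",
                                             "amplitudes.csv",
                                             "separation.json")))))
  meta <- jsonlite::read_json(file.path(d, "separation.json"))
  expect_equal(meta$iterations, sep$iterations)
  ph <- utils::read.csv(file.path(d, "phases.csv"))
  expect_equal(ncol(ph), 6L)  # t + one column per curve
})
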