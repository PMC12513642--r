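test_that("generated warps are admissible across the intensity range", {
  set.seed(91)
  expect_error(make_warp(1), "\\[0, 1\\)")
  expect_error(make_warp(-0.1), "\\[0, 1\\)")
  w0 <- make_warp(0)
  expect_equal(w0$values, w0$grid)
  for (i in 1:1000) {
    w <- make_warp(0.9, n = 50L)
    expect_true(all(diff(w$values) > 0))
    a <- attr(w, "a")
    # derivative 1 + a cos(pi t) strictly positive on the grid
    expect_true(all(1 + a * cos(pi * w$grid) > 0))
  }
})

test_that("templates obey their documented closed forms", {
  for (act in c("curl", "knock")) {
    tpl <- make_template(act, speed = 1, asymmetry = 0)
    # symmetric template: peak and trough magnitudes equal
    expect_equal(max(tpl$values), -min(tpl$values), tolerance = 1e-9)
    # doubling speed doubles the sup norm (to grid-sampling accuracy:
    # the two grids sample the analytic extrema slightly differently)
    t2 <- make_template(act, speed = 2, asymmetry = 0.3)
    t1 <- make_template(act, speed = 1, asymmetry = 0.3)
    expect_equal(max(abs(t2$values)), 2 * max(abs(t1$values)),
                 tolerance = 1e-3)
  }
  expect_error(make_template("curl", speed = 0), "positive")
  expect_error(make_template("curl", asymmetry = 1), "asymmetry")
  # curl peak (1 - a), trough -(1 + a) at unit speed
  a <- 0.4
  tpl <- make_template("curl", speed = 1, asymmetry = a)
  expect_equal(max(tpl$values), 1 - a, tolerance = 1e-3)
  expect_equal(min(tpl$values), -(1 + a), tolerance = 1e-3)
})

test_that("cohort generation is deterministic and respects the config", {
  cfg <- cohort_config(n_subjects = c(DMD = 3L, Healthy = 2L),
                       visits = c(2L, 2L), seed = 42L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(lapply(c1$curves, `[[`, "values"),
                   lapply(c2$curves, `[[`, "values"))
  expect_identical(c1$clinical, c2$clinical)
  # counts: subjects x visits x activities
  expect_length(c1$curves, 5L * 2L * 2L)
  expect_equal(nrow(c1$clinical), 5L)
  expect_true(all(is.na(c1$clinical$brooke[c1$clinical$cohort == "Healthy"])))
  expect_true(all(c1$clinical$brooke[c1$clinical$cohort == "DMD"] %in% 1:6))
  # every emitted warp is admissible
  expect_true(all(abs(c1$truth$repetitions$warp_a) < cfg$warp_intensity))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(cohort_config(warp_intensity = 1), "warp_intensity")
  expect_error(cohort_config(noise_sd = -1), "SDs")
  expect_error(cohort_config(visits = c(0L, 2L)), "visits")
})

test_that("a clean cohort separates into identity phases and equal shapes", {
  cfg <- cohort_config(n_subjects = c(DMD = 4L), visits = c(1L, 1L),
                       activities = "curl", warp_intensity = 0,
                       noise_sd = 0, visit_sd = c(speed = 0, asym = 0),
                       speed_sd = c(DMD = 0), asym_sd = c(DMD = 0),
                       age_slope = c(DMD = 0), seed = 93L)
  co <- generate_cohort(cfg)
  sep <- separate_phase_amplitude(co$curves)
  for (p in sep$phases)
    expect_lt(max(abs(p$values - p$grid)), 3 / 199)
  # same-latent subjects are at (numerically) zero amplitude distance
  expect_lt(amplitude_distance(co$curves[[1]], co$curves[[2]]), 1e-6)
})

test_that("the bump ensemble reduces to amplitude-only at zero intensity", {
  be <- bump_ensemble(8, 0, seed = 94L)
  peaks <- vapply(be$curves, function(b) b$grid[which.max(b$values)], 0)
  expect_true(all(peaks == peaks[1]))  # all curves peak at the template peak
  for (i in seq_along(be$curves))
    expect_equal(be$curves[[i]]$values,
                 be$amplitudes[i] * be$template$values, tolerance = 1e-12)
  # warped ensembles carry admissible warps and full ground truth
  be2 <- bump_ensemble(8, 0.8, seed = 94L)
  for (w in be2$warps) expect_true(all(diff(w$values) > 0))
  expect_length(be2$warps, 8L)
})

test_that("feature simulation honours its SNR and weight contract", {
  sf <- simulate_features(5000, snr = 3, seed = 95L)
  expect_equal(sum(sf$weights^2), 1, tolerance = 1e-12)
  # per-column signal variance ratio approximately 3:1
  u <- sf$latent
  for (j in 1:3) {
    noise <- sf$Y[, j] - u
    expect_equal(stats::var(u) / stats::var(noise), 3, tolerance = 0.2)
  }
})
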