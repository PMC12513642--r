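# Shared fixtures: small libraries of smooth test curves and admissible
# warps, built in code with fixed seeds.

unit_grid <- function(n = 200L) seq(0, 1, length.out = n)

# a library of smooth, structurally varied curves on the unit grid
smooth_curve_library <- function(n = 200L) {
  g <- unit_grid(n)
  list(
    trajectory(sin(2 * pi * g) * exp(-(g - 0.5)^2 / 0.05), g),
    trajectory(exp(-(g - 0.4)^2 / 0.01) - 0.6 * exp(-(g - 0.7)^2 / 0.02), g),
    trajectory(g^2 - g + 0.3 * sin(3 * pi * g), g),
    trajectory(cos(2 * pi * g) * (1 - g), g),
    trajectory(2 * exp(-(g - 0.5)^2 / 0.02), g)
  )
}

# sinusoidal warp with a fixed coefficient (no RNG)
fixed_warp <- function(a, n = 200L) {
  g <- unit_grid(n)
  warp_fn(g + a * sin(pi * g) / pi, g)
}

# random smooth curve from a low-order Fourier series
random_smooth_curve <- function(n = 200L, k = 4L) {
  g <- unit_grid(n)
  v <- rep(0, n)
  for (j in seq_len(k))
    v <- v + stats::rnorm(1, 0, 1 / j) * sin(j * pi * g) +
      stats::rnorm(1, 0, 1 / j) * cos(j * pi * g)
  trajectory(v - v[1] + stats::rnorm(1), g)
}

expect_trajectory_equal <- function(a, b, tol = 1e-8) {
  expect_equal(a$values, b$values, tolerance = tol)
  expect_equal(a$grid, b$grid, tolerance = tol)
}
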