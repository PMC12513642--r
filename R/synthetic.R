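# Synthetic cohort generator: curl-like and knock-like angular-velocity
# templates, sinusoidal random time warps, cohort-dependent speed/asymmetry
# latents, multi-visit structure, and clinical covariates tied linearly to
# the latents. Every emitted quantity has recorded ground truth so each
# pipeline stage can be validated without real sensor data.

#' Random sinusoidal time warp
#'
#' Draws \eqn{\gamma(t) = t + a\,\sin(\pi t)/\pi} with
#' \eqn{a \sim U(-\mathrm{intensity}, \mathrm{intensity})} on a unit-interval
#' grid. For \eqn{|a| < 1} the derivative \eqn{1 + a\cos(\pi t)} is strictly
#' positive, so the warp is admissible (boundary-pinned, strictly
#' increasing). Uses the current RNG stream; seed upstream for
#' reproducibility.
#'
#' @param intensity warp intensity in `[0, 1)`; 0 gives the identity warp.
#' @param n grid length (default 200).
#' @return a [warp_fn()].
#' @export
make_warp <- function(intensity, n = 200L) {
  if (!is.finite(intensity) || intensity < 0 || intensity >= 1)
    stop("warp intensity must lie in [0, 1)", call. = FALSE)
  g <- seq(0, 1, length.out = n)
  a <- if (intensity == 0) 0 else stats::runif(1L, -intensity, intensity)
  w <- warp_fn(g + a * sin(pi * g) / pi, g)
  attr(w, "a") <- a
  w
}

#' Noise-free movement template
#'
#' Deterministic angular-velocity templates with two interpretable latents.
#' `curl`: one positive lobe followed by one negative lobe (a normalized
#' Gaussian derivative); `knock`: two oscillation cycles (a Gaussian-windowed
#' sine). The `speed` latent scales the amplitude linearly and mildly
#' compresses the movement in time around the midpoint (width proportional
#' to `1/sqrt(speed)`; a faster movement is taller and somewhat narrower),
#' so doubling `speed` doubles the maximal angular velocity. The
#' `asymmetry` latent scales the positive-going part by `(1 - asymmetry)`
#' and the negative-going part by `(1 + asymmetry)` (for `knock`, the first
#' and second oscillation cycle): a weakened upward phase together with a
#' faster, gravity-assisted downward phase. For a curl template at
#' `speed = 1` the peak is `1 - asymmetry` and the trough
#' `-(1 + asymmetry)`, so [asymmetry_statistic()] equals `-asymmetry` in
#' closed form. The balanced contrast keeps the asymmetry direction
#' orthogonal to pure scaling, so the two latents generate distinct modes
#' of shape variation.
#'
#' @param activity `"curl"` or `"knock"`.
#' @param speed positive speed latent (1 = reference).
#' @param asymmetry asymmetry latent in `(-1, 1)` (0 = symmetric).
#' @param n grid length (default 200).
#' @return a [trajectory()] on the unit grid.
#' @export
make_template <- function(activity = c("curl", "knock"), speed = 1,
                          asymmetry = 0, n = 200L) {
  activity <- match.arg(activity)
  if (!is.finite(speed) || speed <= 0)
    stop("speed must be positive", call. = FALSE)
  if (!is.finite(asymmetry) || abs(asymmetry) >= 1)
    stop("|asymmetry| must be < 1", call. = FALSE)
  g <- seq(0, 1, length.out = n)
  u <- 0.5 + (g - 0.5) * sqrt(speed)
  if (activity == "curl") {
    s <- 0.12
    raw <- -(u - 0.5) / s^2 * exp(-(u - 0.5)^2 / (2 * s^2))
    base <- raw / (exp(-0.5) / s)        # normalized: extrema at +/- 1
  } else {
    env <- exp(-(u - 0.5)^2 / (2 * 0.18^2))
    base <- env * sin(4 * pi * (u - 0.5))
    base <- base / max(abs(base))
  }
  up <- if (activity == "curl") base > 0 else u < 0.5
  v <- ifelse(up, (1 - asymmetry) * base, (1 + asymmetry) * base)
  trajectory(speed * v, g, activity = activity)
}

#' Configuration of a synthetic cohort
#'
#' Collects the generator's knobs with defaults mirroring the study design
#' this package targets: three cohorts (DMD n = 15, SMA n = 7, Healthy
#' n = 9), one to three visits per subject, curl and knock activities on a
#' 200-point grid. Per cohort, subject speed and asymmetry latents are drawn
#' from normal distributions (patients slower and, for SMA especially, more
#' asymmetric; patient speed declines with age). Each repetition applies a
#' visit-level latent jitter, a random sinusoidal warp, and i.i.d.
#' observation noise. Clinical covariates are noisy linear functions of the
#' latents: Brooke (patients only, ordinal 1-6) and echogenicity increase as
#' speed drops and asymmetry rises, torque tracks speed.
#'
#' @param n_subjects named integer vector of cohort sizes.
#' @param visits integer range (min, max) of visits per subject.
#' @param n_grid grid length.
#' @param activities subset of `c("curl", "knock")`.
#' @param speed_mean,speed_sd,asym_mean,asym_sd named per-cohort latent
#'   means/SDs.
#' @param age_slope named per-cohort change of the speed latent per year of
#'   age (0 for Healthy).
#' @param age_range named list of per-cohort age ranges (years).
#' @param warp_intensity sinusoidal warp intensity in `[0, 1)`.
#' @param noise_sd observation noise SD (deg/s, on curves of unit scale).
#' @param visit_sd named SDs of the per-visit latent jitter
#'   (`speed`, `asym`).
#' @param seed integer seed fully determining the cohort.
#' @return a list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = c(DMD = 15L, SMA = 7L, Healthy = 9L),
                          visits = c(1L, 3L),
                          n_grid = 200L,
                          activities = c("curl", "knock"),
                          speed_mean = c(DMD = 0.85, SMA = 0.75, Healthy = 1.15),
                          speed_sd = c(DMD = 0.25, SMA = 0.25, Healthy = 0.18),
                          asym_mean = c(DMD = 0.12, SMA = 0.30, Healthy = 0.05),
                          asym_sd = c(DMD = 0.10, SMA = 0.12, Healthy = 0.08),
                          age_slope = c(DMD = -0.010, SMA = -0.015, Healthy = 0),
                          age_range = list(DMD = c(4, 35), SMA = c(2, 19),
                                           Healthy = c(2, 35)),
                          warp_intensity = 0.4,
                          noise_sd = 0.03,
                          visit_sd = c(speed = 0.06, asym = 0.04),
                          seed = 1L) {
  cfg <- list(n_subjects = n_subjects, visits = as.integer(visits),
              n_grid = as.integer(n_grid), activities = activities,
              speed_mean = speed_mean, speed_sd = speed_sd,
              asym_mean = asym_mean, asym_sd = asym_sd,
              age_slope = age_slope, age_range = age_range,
              warp_intensity = warp_intensity, noise_sd = noise_sd,
              visit_sd = visit_sd, seed = as.integer(seed))
  if (any(c(cfg$speed_sd, cfg$asym_sd, cfg$noise_sd, cfg$visit_sd) < 0))
    stop("all SDs must be >= 0", call. = FALSE)
  if (cfg$warp_intensity < 0 || cfg$warp_intensity >= 1)
    stop("warp_intensity must lie in [0, 1)", call. = FALSE)
  if (any(cfg$visits < 1L) || cfg$visits[2] < cfg$visits[1])
    stop("visits must be an increasing range of integers >= 1", call. = FALSE)
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic cohort
#'
#' Draws subject latents, visit structure, warped noisy repetitions, and
#' clinical covariates according to a [cohort_config()]; fully determined by
#' the config's seed. See the config documentation for the generative model.
#'
#' @param config a [cohort_config()].
#' @return list with `curves` (list of [trajectory()]), `clinical` (data
#'   frame: `subject_id`, `cohort`, `age`, `brooke` (`NA` for Healthy),
#'   `avg_echo`, `net`), and `truth` (list with per-subject latent table and
#'   per-repetition warp amplitudes).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  with_seed(cfg$seed, {
    subj <- list(); clin <- list(); curves <- list(); warp_a <- list()
    sid <- 0L
    for (coh in names(cfg$n_subjects)) {
      for (i in seq_len(cfg$n_subjects[[coh]])) {
        sid <- sid + 1L
        id <- sprintf("S%03d", sid)
        ar <- cfg$age_range[[coh]]
        age <- stats::runif(1L, ar[1], ar[2])
        speed <- stats::rnorm(1L, cfg$speed_mean[[coh]] +
                                cfg$age_slope[[coh]] * (age - mean(ar)),
                              cfg$speed_sd[[coh]])
        speed <- max(speed, 0.25)
        asym <- stats::rnorm(1L, cfg$asym_mean[[coh]], cfg$asym_sd[[coh]])
        asym <- min(max(asym, -0.85), 0.85)
        n_vis <- if (cfg$visits[1] == cfg$visits[2]) cfg$visits[1] else
          sample(seq(cfg$visits[1], cfg$visits[2]), 1L)
        subj[[sid]] <- data.frame(subject_id = id, cohort = coh, age = age,
                                  speed = speed, asym = asym,
                                  n_visits = n_vis, stringsAsFactors = FALSE)
        brooke <- if (coh == "Healthy") NA_real_ else
          min(max(round(1.5 + 3.5 * (1.1 - speed) + 1.2 * asym +
                          stats::rnorm(1L, 0, 0.5)), 1), 6)
        avg_echo <- 55 + 35 * (1.15 - speed) + 12 * asym +
          0.3 * (age - 12) + stats::rnorm(1L, 0, 4)
        net <- max(0.25 * speed + stats::rnorm(1L, 0, 0.03), 0.01)
        clin[[sid]] <- data.frame(subject_id = id, cohort = coh, age = age,
                                  brooke = brooke, avg_echo = avg_echo,
                                  net = net, stringsAsFactors = FALSE)
        for (v in seq_len(n_vis)) {
          sp_v <- max(speed + stats::rnorm(1L, 0, cfg$visit_sd[["speed"]]),
                      0.2)
          as_v <- min(max(asym + stats::rnorm(1L, 0, cfg$visit_sd[["asym"]]),
                          -0.9), 0.9)
          for (act in cfg$activities) {
            tpl <- make_template(act, speed = sp_v, asymmetry = as_v,
                                 n = cfg$n_grid)
            gam <- make_warp(cfg$warp_intensity, n = cfg$n_grid)
            b <- warp_trajectory(tpl, gam)
            b$values <- b$values + stats::rnorm(cfg$n_grid, 0, cfg$noise_sd)
            b$subject_id <- id; b$visit <- v; b$activity <- act
            curves[[length(curves) + 1L]] <- b
            warp_a[[length(warp_a) + 1L]] <- data.frame(
              subject_id = id, visit = v, activity = act,
              warp_a = attr(gam, "a"), speed_visit = sp_v,
              asym_visit = as_v, stringsAsFactors = FALSE)
          }
        }
      }
    }
  })
  list(curves = curves,
       clinical = do.call(rbind, clin),
       truth = list(subjects = do.call(rbind, subj),
                    repetitions = do.call(rbind, warp_a),
                    config = cfg))
}

#' Symmetric-bump ensemble with amplitude and phase variability
#'
#' Builds the canonical demonstration of why phase variability breaks the
#' cross-sectional mean: a symmetric Gaussian bump template is scaled by
#' per-curve amplitudes and then warped by random sinusoidal warps. The
#' Euclidean mean of the warped family smears and distorts the bump, while
#' the Karcher mean recovers the symmetric shape.
#'
#' Two design choices make the ensemble behave like repeated movements of a
#' real cohort rather than arbitrary noise. First, the drawn warp
#' coefficients are centred so the ensemble carries no net phase drift:
#' warps represent relative timing variability about a common timing, which
#' is also what makes "the mean shape is symmetric" a well-posed statement
#' (the symmetric representative is the one whose phases average to
#' identity). Second, amplitude and rate are coupled: a repetition that
#' drifts late (positive warp coefficient) is also performed slightly
#' larger, as slower, larger movements co-occur in practice
#' (`A_i = 1 + 0.25 a_i / intensity + U(-0.1, 0.1)`). The coupling gives the
#' Euclidean mean a systematic skew (the textbook failure mode) instead of
#' one that averages away, without touching the shapes themselves. With
#' `warp_intensity = 0` all warps are the identity and the family has
#' amplitude variability only, every curve peaking at the template's peak.
#'
#' @param n number of curves (>= 3).
#' @param warp_intensity sinusoidal warp intensity in `[0, 1)`.
#' @param seed integer seed.
#' @param n_grid grid length (default 200).
#' @return list with `curves` (warped), `unwarped` (amplitude-only family),
#'   `warps` (true [warp_fn()]s), `template` (unit-amplitude symmetric
#'   bump), `amplitudes`.
#' @export
bump_ensemble <- function(n, warp_intensity, seed, n_grid = 200L) {
  stopifnot(n >= 3L)
  if (warp_intensity < 0 || warp_intensity >= 1)
    stop("warp intensity must lie in [0, 1)", call. = FALSE)
  g <- seq(0, 1, length.out = n_grid)
  tpl <- trajectory(exp(-(g - 0.5)^2 / (2 * 0.1^2)), g)
  with_seed(seed, {
    a_norm <- stats::runif(n, -1, 1)
    # no net phase drift: centre, then rescale back into [-1, 1]
    a_norm <- (a_norm - mean(a_norm)) / (1 + abs(mean(a_norm)))
    amps <- 1 + 0.25 * a_norm + stats::runif(n, -0.1, 0.1)
  })
  warps <- lapply(a_norm * warp_intensity, function(a) {
    warp_fn(g + a * sin(pi * g) / pi, g)
  })
  unwarped <- lapply(amps, function(a) trajectory(a * tpl$values, g))
  curves <- Map(function(b, w) warp_trajectory(b, w), unwarped, warps)
  list(curves = curves, unwarped = unwarped, warps = warps,
       template = tpl, amplitudes = amps)
}

#' Feature-level generator for validating the PLS index
#'
#' Generates wearable-like features `X` with i.i.d. standard-normal columns,
#' a latent score `u = X w` with known unit-norm weights, and clinical
#' variables `Y = u 1' + noise` whose per-column signal-to-noise variance
#' ratio is `snr`. Used to check that PLS recovers the generating weights
#' and that the bootstrapped canonical correlation matches a large-sample
#' population value.
#'
#' @param n number of subjects.
#' @param weights generating X-side weight vector (normalized internally).
#' @param n_y number of clinical columns (default 3).
#' @param snr per-column signal-to-noise variance ratio (default 3).
#' @param seed integer seed.
#' @return list with `X`, `Y`, `weights` (unit norm), `latent`.
#' @export
simulate_features <- function(n, weights = c(0.76, -0.59, 0.18, 0.18),
                              n_y = 3L, snr = 3, seed = 1L) {
  w <- weights / sqrt(sum(weights^2))
  p <- length(w)
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    u <- drop(X %*% w)
    E <- matrix(stats::rnorm(n * n_y, 0, sqrt(1 / snr)), n, n_y)
    Y <- u %*% t(rep(1, n_y)) + E
  })
  colnames(Y) <- paste0("y", seq_len(n_y))
  list(X = X, Y = Y, weights = w, latent = u)
}
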