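make_visit_scores <- function(slopes = c(Healthy = 0, DMD = 1, SMA = 2),
                              n_per = 15L, visits = 3L, noise = 0.5,
                              icc_sd = 0.5, seed = 1L) {
  set.seed(seed)
  coh <- rep(names(slopes), each = n_per)
  n <- length(coh)
  ids <- sprintf("P%03d", seq_len(n))
  ages <- stats::runif(n, 4, 16)
  scores <- do.call(rbind, lapply(seq_len(n), function(i) {
    a0 <- stats::rnorm(1, 0, icc_sd)
    data.frame(subject_id = ids[i], visit = seq_len(visits),
               score = a0 + slopes[[coh[i]]] * ages[i] +
                 stats::rnorm(visits, 0, noise),
               stringsAsFactors = FALSE)
  }))
  clinical <- data.frame(subject_id = ids, cohort = coh, age = ages,
                         stringsAsFactors = FALSE)
  list(scores = scores, clinical = clinical)
}

test_that("bootstrap PLS is bit-identical under a fixed seed", {
  sf <- simulate_features(60, snr = 3, seed = 61)
  b1 <- bootstrap_pls(sf$X, sf$Y, n_boot = 200L, seed = 7L)
  b2 <- bootstrap_pls(sf$X, sf$Y, n_boot = 200L, seed = 7L)
  expect_identical(b1$boot_cor, b2$boot_cor)
  expect_identical(b1$boot_x_weights, b2$boot_x_weights)
  b3 <- bootstrap_pls(sf$X, sf$Y, n_boot = 200L, seed = 8L)
  expect_false(identical(b1$boot_cor, b3$boot_cor))
})

test_that("bootstrap correlations are bounded and intervals are nested", {
  sf <- simulate_features(60, snr = 1, seed = 62)
  b <- bootstrap_pls(sf$X, sf$Y, n_boot = 300L, seed = 9L, n_components = 2L)
  cors <- b$boot_cor[!is.na(b$boot_cor)]
  expect_true(all(cors >= -1 & cors <= 1))
  for (h in 1:2) {
    expect_lte(b$ci95["lower", h], b$ci90["lower", h])
    expect_gte(b$ci95["upper", h], b$ci90["upper", h])
    expect_gte(b$median[h], b$ci90["lower", h])
    expect_lte(b$median[h], b$ci90["upper", h])
  }
})

test_that("independent Y gives a near-zero test correlation distribution", {
  set.seed(63)
  X <- matrix(rnorm(100 * 4), 100, 4)
  Y <- matrix(rnorm(100 * 3), 100, 3)
  b <- suppressWarnings(bootstrap_pls(X, Y, n_boot = 1000L, seed = 10L))
  expect_lt(abs(b$median[1]), 0.15)
})

test_that("a noiseless linear Y gives a degenerate unit distribution", {
  set.seed(64)
  X <- matrix(rnorm(40 * 4), 40, 4)
  Y <- X %*% diag(c(1, -2, 0.5, 1.5))
  b <- bootstrap_pls(X, Y, n_boot = 200L, seed = 11L)
  expect_equal(unname(b$median[1]), 1, tolerance = 1e-6)
  expect_lt(b$ci90["upper", 1] - b$ci90["lower", 1], 0.05)
})

test_that("the repeated-visit embedding collapses to single-run scores", {
  co <- generate_cohort(cohort_config(
    n_subjects = c(DMD = 4L, Healthy = 3L), visits = c(1L, 1L),
    noise_sd = 0.005, seed = 77L))
  curves <- lapply(co$curves, smooth_trajectory)
  emb <- suppressWarnings(
    repeated_shape_pca(curves, n_runs = 3L, seed = 5L, n_retained = 2L))
  feats <- attr(emb, "features")
  # single visit: every run identical, dispersion exactly zero
  for (f in feats) expect_equal(emb[[paste0(f, "_sd")]], rep(0, nrow(emb)))
  # and the embedding is reproducible
  emb2 <- suppressWarnings(
    repeated_shape_pca(curves, n_runs = 3L, seed = 5L, n_retained = 2L))
  expect_identical(emb, emb2)
})

test_that("within-subject visit noise shrinks across-run dispersion", {
  co <- generate_cohort(cohort_config(
    n_subjects = c(DMD = 12L), visits = c(2L, 2L), activities = "curl",
    visit_sd = c(speed = 0.03, asym = 0.02), noise_sd = 0.005, seed = 78L))
  curves <- lapply(co$curves, smooth_trajectory)
  emb <- suppressWarnings(
    repeated_shape_pca(curves, n_runs = 8L, seed = 6L, n_retained = 1L))
  disp <- mean(emb$VPC1_curl_sd)
  spread <- stats::sd(emb$VPC1_curl)
  expect_lt(disp / spread, 0.5)
})

test_that("subjects missing an activity are excluded with a warning", {
  co <- generate_cohort(cohort_config(
    n_subjects = c(DMD = 4L), visits = c(1L, 1L), noise_sd = 0.005,
    seed = 79L))
  curves <- co$curves
  drop <- vapply(curves, function(b)
    b$subject_id == "S001" && b$activity == "knock", TRUE)
  expect_warning(
    emb <- repeated_shape_pca(curves[!drop], n_runs = 2L, seed = 3L),
    "excluding")
  expect_false("S001" %in% emb$subject_id)
})

test_that("the Pearson panel matches the covariance formula", {
  set.seed(65)
  emb <- data.frame(subject_id = sprintf("S%02d", 1:12),
                    VPC1_curl = rnorm(12), VPC2_curl = rnorm(12))
  clin <- data.frame(subject_id = emb$subject_id,
                     cohort = rep(c("DMD", "Healthy"), each = 6),
                     age = rnorm(12, 10, 3),
                     brooke = c(sample(1:6, 6, TRUE), rep(NA, 6)),
                     avg_echo = rnorm(12, 60, 10),
                     net = rnorm(12, 0.2, 0.05))
  clin$net[3] <- emb$VPC1_curl[3] * 0.05 + 0.2  # arbitrary values
  pan <- pearson_panel(emb, clin, features = c("VPC1_curl", "VPC2_curl"))
  # Brooke never reported for Healthy
  expect_false(any(pan$cohort == "Healthy" & pan$clinical_var == "brooke"))
  # against the raw covariance formula
  d <- merge(emb, clin, by = "subject_id")
  dd <- d[d$cohort == "DMD", ]
  r_oracle <- sum((dd$VPC1_curl - mean(dd$VPC1_curl)) *
                    (dd$age - mean(dd$age))) /
    sqrt(sum((dd$VPC1_curl - mean(dd$VPC1_curl))^2) *
           sum((dd$age - mean(dd$age))^2))
  got <- pan$r[pan$cohort == "DMD" & pan$feature == "VPC1_curl" &
                 pan$clinical_var == "age"]
  expect_equal(got, r_oracle, tolerance = 1e-12)
  # perfect and antithetic pairs
  emb$VPC2_curl <- clin$avg_echo
  pan2 <- pearson_panel(emb, clin, features = "VPC2_curl")
  expect_equal(pan2$r[pan2$clinical_var == "avg_echo"], c(1, 1))
  emb$VPC2_curl <- -clin$avg_echo
  pan3 <- pearson_panel(emb, clin, features = "VPC2_curl")
  expect_equal(pan3$r[pan3$clinical_var == "avg_echo"], c(-1, -1))
  # zero-variance input is undefined, not zero
  emb$VPC2_curl <- 1
  pan4 <- pearson_panel(emb, clin, features = "VPC2_curl")
  expect_true(all(is.na(pan4$r)))
})

test_that("the mixed model recovers cohort slopes with Wald inference", {
  sim <- make_visit_scores(seed = 66L)
  tab <- age_mixed_model(sim$scores, sim$clinical)
  est <- tab$estimate[tab$term == "age:cohortDMD"]
  se <- tab$se[tab$term == "age:cohortDMD"]
  expect_lt(abs(est - 1), 3 * se)
  expect_true(tab$significant[tab$term == "age:cohortDMD"])
  expect_true(tab$significant[tab$term == "age:cohortSMA"])
  expect_false(tab$significant[tab$term == "age"])
  # Wald p-values follow from the normal tail
  expect_equal(tab$p, 2 * pnorm(-abs(tab$estimate / tab$se)),
               tolerance = 1e-12)
})

test_that("BH adjustment in the report matches the hand-computed oracle", {
  sim <- make_visit_scores(seed = 67L)
  tab <- age_mixed_model(sim$scores, sim$clinical)
  idx <- tab$term != "(Intercept)"
  p <- tab$p[idx]
  m <- length(p)
  o <- order(p)
  hand <- numeric(m)
  hand[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  hand <- pmin(hand, 1)
  expect_equal(tab$p_adj[idx], hand, tolerance = 1e-12)
  expect_true(all(is.na(tab$p_adj[!idx])))
})

test_that("the baseline table has the expected structure", {
  co <- generate_cohort(cohort_config(
    n_subjects = c(DMD = 10L, SMA = 6L), visits = c(1L, 1L),
    noise_sd = 0.005, seed = 80L))
  curves <- lapply(co$curves, smooth_trajectory)
  tab <- suppressWarnings(baseline_comparison(
    curves, co$clinical, n_boot = 100L, seed = 12L, n_components = 2L))
  expect_equal(nrow(tab), 3L * 2L)
  expect_setequal(unique(tab$method), c("shape", "fpca", "nmf"))
  expect_true(all(tab$q05 <= tab$median & tab$median <= tab$q95))
})
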