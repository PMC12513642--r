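# Statistical layer: repeated shape PCA embedding, bootstrapped PLS index,
# correlation panels, age x cohort mixed model, and baseline comparison.

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards; all stochastic stages use this, so a run is
# fully determined by its seed and never perturbs the session RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Repeated random-visit shape PCA embedding
#'
#' Subjects contribute a variable number of visits. To keep one row per
#' subject without discarding data, shape PCA is refitted `n_runs` times,
#' each time with one uniformly sampled visit per subject; the components of
#' every run are sign-aligned to those of the first run (a component is
#' flipped when its inner product with the first run's matching component is
#' negative), the selected curves are projected, and the per-subject scores
#' are averaged across runs. The across-run standard deviation is returned
#' alongside as a dispersion diagnostic.
#'
#' @param curves list of [trajectory()] objects carrying `subject_id`,
#'   `visit` and `activity`; every retained subject needs at least one visit
#'   of every activity present (others are excluded with a warning).
#' @param n_runs number of random-visit refits (default 100).
#' @param seed integer seed; the embedding is fully determined by it.
#' @param n_retained VPCs retained per activity (default 2: speed and
#'   asymmetry feed the index).
#' @param refit if `TRUE` (default) the Karcher mean and alignment are
#'   refitted in every run; if `FALSE` a single alignment/PCA of all curves
#'   is fitted once and runs only resample which visit's projections enter
#'   the average (much faster).
#' @param tol,max_iter passed to [karcher_mean()].
#' @return a data frame with one row per subject: `subject_id`, mean VPC
#'   scores per feature (e.g. `VPC1_curl`), their across-run standard
#'   deviations (`*_sd`), and attribute `n_runs`.
#' @export
repeated_shape_pca <- function(curves, n_runs = 100L, seed, n_retained = 2L,
                               refit = TRUE, tol = 5e-3, max_iter = 20L) {
  stopifnot(is.list(curves), length(curves) >= 3L)
  info <- data.frame(
    idx = seq_along(curves),
    subject_id = vapply(curves, `[[`, "", "subject_id"),
    visit = vapply(curves, `[[`, 0L, "visit"),
    activity = vapply(curves, `[[`, "", "activity"),
    stringsAsFactors = FALSE)
  activities <- sort(unique(info$activity))
  subjects <- sort(unique(info$subject_id))
  keep <- vapply(subjects, function(s)
    all(activities %in% info$activity[info$subject_id == s]), TRUE)
  if (any(!keep)) {
    warning(sprintf("excluding %d subject(s) with missing activities: %s",
                    sum(!keep), paste(subjects[!keep], collapse = ", ")))
    subjects <- subjects[keep]
  }
  n_sub <- length(subjects)
  feat_names <- as.vector(t(outer(activities,
                                  paste0("VPC", seq_len(n_retained)),
                                  function(a, v) paste0(v, "_", a))))

  base_models <- NULL
  base_scores <- NULL
  if (!refit) {
    # one alignment/PCA per activity over all curves; runs only resample
    base_models <- list(); base_scores <- list()
    for (act in activities) {
      rows <- info[info$activity == act, ]
      sep <- separate_phase_amplitude(curves[rows$idx], tol = tol,
                                      max_iter = max_iter)
      pca <- fit_shape_pca(sep, n_retained = n_retained)
      sc <- pca$scores
      rownames(sc) <- paste(rows$subject_id, rows$visit, sep = "\r")
      base_models[[act]] <- pca
      base_scores[[act]] <- sc
    }
  }

  run_scores <- array(NA_real_, c(n_sub, length(feat_names), n_runs),
                      dimnames = list(subjects, feat_names, NULL))
  ref_components <- list()
  with_seed(seed, {
    for (run in seq_len(n_runs)) {
      for (act in activities) {
        rows <- info[info$activity == act & info$subject_id %in% subjects, ]
        pick <- vapply(subjects, function(s) {
          cand <- rows$idx[rows$subject_id == s]
          if (length(cand) == 1L) cand else sample(cand, 1L)
        }, 0L)
        cols <- paste0("VPC", seq_len(n_retained), "_", act)
        if (refit) {
          sep <- separate_phase_amplitude(curves[pick], tol = tol,
                                          max_iter = max_iter)
          pca <- fit_shape_pca(sep, n_retained = n_retained)
          comp <- pca$components
          sc <- pca$scores
          if (run == 1L) {
            ref_components[[act]] <- comp
          } else {
            ref <- ref_components[[act]]
            for (kk in seq_len(n_retained)) {
              if (sum(comp[, kk] * ref[, kk]) < 0) sc[, kk] <- -sc[, kk]
            }
          }
          run_scores[, cols, run] <- sc
        } else {
          key <- paste(subjects, info$visit[pick], sep = "\r")
          run_scores[, cols, run] <- base_scores[[act]][key, , drop = FALSE]
        }
      }
    }
  })
  means <- apply(run_scores, c(1L, 2L), mean)
  sds <- apply(run_scores, c(1L, 2L), stats::sd)
  out <- data.frame(subject_id = subjects, means, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (f in feat_names) out[[paste0(f, "_sd")]] <- sds[, f]
  attr(out, "n_runs") <- n_runs
  attr(out, "features") <- feat_names
  out
}

#' Bootstrapped PLS canonical index
#'
#' Quantifies the sampling variability of the PLS index by subject-level
#' bootstrap. In each replicate, `round(train_frac * n)` subjects are drawn
#' with replacement as a training set; subjects never drawn form the
#' hold-out set. PLS is fitted on the training subjects and the Pearson
#' correlation of the paired latent scores of the hold-out subjects is
#' recorded per component (the test canonical correlation). Replicates with
#' a degenerate hold-out (< 3 subjects, a zero-variance score, or a dropped
#' column) are skipped and counted. Replicate weight vectors are flipped to
#' have positive inner product with the full-data point fit so coefficient
#' distributions are comparable across replicates.
#'
#' @inheritParams fit_pls
#' @param n_boot number of bootstrap replicates (default 10000).
#' @param train_frac fraction of subjects (with replacement) in each
#'   training draw (default 0.7).
#' @param seed integer seed; with a fixed seed the full correlation and
#'   coefficient distributions are bit-identical across calls.
#' @return an object of class `"motor_index"`: the full-data `point_fit`, the
#'   replicate test-correlation matrix `boot_cor` (`n_boot` x components,
#'   `NA` for skipped replicates), first-component weight distributions
#'   (`boot_x_weights`, `boot_y_weights`), medians and both 2.5--97.5 and
#'   5--95 percentile intervals, and the skip count.
#' @export
bootstrap_pls <- function(X, Y, n_boot = 10000L, train_frac = 0.7, seed,
                          n_components = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  cc <- stats::complete.cases(X) & stats::complete.cases(Y)
  X <- X[cc, , drop = FALSE]; Y <- Y[cc, , drop = FALSE]
  n <- nrow(X)
  point_fit <- fit_pls(X, Y, n_components = n_components)
  k <- point_fit$n_components
  boot_cor <- matrix(NA_real_, n_boot, k)
  bw <- matrix(NA_real_, n_boot, nrow(point_fit$x_weights),
               dimnames = list(NULL, rownames(point_fit$x_weights)))
  bc <- matrix(NA_real_, n_boot, nrow(point_fit$y_weights),
               dimnames = list(NULL, rownames(point_fit$y_weights)))
  n_train <- max(5L, round(train_frac * n))
  n_skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n_train, replace = TRUE)
      test <- setdiff(seq_len(n), unique(idx))
      if (length(test) < 3L) { n_skipped <- n_skipped + 1L; next }
      fit <- tryCatch(
        suppressWarnings(fit_pls(X[idx, , drop = FALSE],
                                 Y[idx, , drop = FALSE],
                                 n_components = k)),
        error = function(e) NULL)
      if (is.null(fit) || fit$n_components < k ||
          nrow(fit$x_weights) < nrow(point_fit$x_weights) ||
          nrow(fit$y_weights) < nrow(point_fit$y_weights)) {
        n_skipped <- n_skipped + 1L; next
      }
      sc <- predict(fit, X[test, , drop = FALSE], Y[test, , drop = FALSE])
      sds_x <- apply(sc$x_scores, 2L, stats::sd)
      sds_y <- apply(sc$y_scores, 2L, stats::sd)
      if (any(sds_x == 0) || any(sds_y == 0)) {
        n_skipped <- n_skipped + 1L; next
      }
      # sign-align to the point fit (joint flip leaves correlations intact)
      w1 <- fit$x_weights[, 1L]
      if (sum(w1 * point_fit$x_weights[, 1L]) < 0) {
        w1 <- -w1
        bc[b, ] <- -fit$y_weights[, 1L]
      } else {
        bc[b, ] <- fit$y_weights[, 1L]
      }
      bw[b, ] <- w1
      boot_cor[b, ] <- vapply(seq_len(k), function(h)
        stats::cor(sc$x_scores[, h], sc$y_scores[, h]), 0)
    }
  })
  qs <- function(M, p) apply(M, 2L, stats::quantile, probs = p, na.rm = TRUE)
  structure(list(point_fit = point_fit, boot_cor = boot_cor,
                 boot_x_weights = bw, boot_y_weights = bc,
                 median = qs(boot_cor, 0.5),
                 ci95 = rbind(lower = qs(boot_cor, 0.025),
                              upper = qs(boot_cor, 0.975)),
                 ci90 = rbind(lower = qs(boot_cor, 0.05),
                              upper = qs(boot_cor, 0.95)),
                 n_boot = n_boot, n_skipped = n_skipped,
                 train_frac = train_frac, seed = seed, n = n),
            class = "motor_index")
}

#' @export
print.motor_index <- function(x, ...) {
  cat(sprintf("<motor_index> %d subjects, %d bootstrap replicates (%d skipped)\n",
              x$n, x$n_boot, x$n_skipped))
  for (h in seq_along(x$median)) {
    cat(sprintf("  component %d: median r = %.2f, [5-95]%% = [%.2f, %.2f]\n",
                h, x$median[h], x$ci90["lower", h], x$ci90["upper", h]))
  }
  cat("  index weights (full-data fit):\n")
  print(round(x$point_fit$x_weights[, 1L], 3))
  invisible(x)
}

#' @export
summary.motor_index <- function(object, ...) {
  data.frame(component = seq_along(object$median),
             median = object$median,
             q025 = object$ci95["lower", ], q975 = object$ci95["upper", ],
             q05 = object$ci90["lower", ], q95 = object$ci90["upper", ],
             row.names = NULL)
}

#' @export
coef.motor_index <- function(object, ...) object$point_fit$x_weights[, 1L]

#' @export
plot.motor_index <- function(x, ...) {
  graphics::hist(x$boot_cor[, 1L], breaks = 40, col = "grey80",
                 main = "bootstrap test canonical correlation (component 1)",
                 xlab = "Pearson r", ...)
  graphics::abline(v = x$median[1L], col = "red", lwd = 2)
  invisible(x)
}

#' Per-cohort Pearson correlation panel
#'
#' Pearson correlations of each wearable feature with each clinical measure,
#' computed per cohort on complete cases. The Brooke score is omitted for
#' the Healthy cohort (it is only collected in patient cohorts). Pairs with
#' fewer than 3 complete cases or a zero-variance member are reported as
#' `NA` (undefined), never as 0.
#'
#' @param embedding subject embedding from [repeated_shape_pca()] (or any
#'   data frame with `subject_id` and feature columns).
#' @param clinical clinical table: `subject_id`, `cohort`, `age`, `brooke`,
#'   `avg_echo`, `net`.
#' @param features feature columns to use (default: the embedding's
#'   `features` attribute, else every `VPC*` column).
#' @param y_vars clinical columns to correlate against.
#' @return long data frame: `cohort`, `feature`, `clinical_var`, `r`, `n`.
#' @export
pearson_panel <- function(embedding, clinical,
                          features = NULL,
                          y_vars = c("age", "brooke", "avg_echo", "net")) {
  if (is.null(features)) {
    features <- attr(embedding, "features")
    if (is.null(features))
      features <- grep("^VPC[0-9]+_", names(embedding), value = TRUE)
    features <- setdiff(features, grep("_sd$", features, value = TRUE))
  }
  d <- merge(embedding, clinical, by = "subject_id")
  out <- list()
  for (coh in unique(d$cohort)) {
    dc <- d[d$cohort == coh, ]
    for (f in features) {
      for (yv in y_vars) {
        if (identical(yv, "brooke") && identical(coh, "Healthy")) next
        ok <- is.finite(dc[[f]]) & is.finite(dc[[yv]])
        r <- NA_real_
        if (sum(ok) >= 3L &&
            stats::sd(dc[[f]][ok]) > 0 && stats::sd(dc[[yv]][ok]) > 0)
          r <- stats::cor(dc[[f]][ok], dc[[yv]][ok])
        out[[length(out) + 1L]] <- data.frame(
          cohort = coh, feature = f, clinical_var = yv, r = r, n = sum(ok),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Age-by-cohort linear mixed model for a VPC score
#'
#' Fits `score ~ age * cohort + (1 | subject_id)` with `lme4::lmer`: a
#' random intercept absorbs repeated visits of the same subject, and the
#' age-by-cohort interaction tests whether a cohort's score drifts with age
#' faster than the reference cohort's (an age-related decline in movement
#' speed when the score is VPC1). Two-sided Wald tests are applied to the
#' fixed effects and Benjamini-Hochberg correction across the non-intercept
#' coefficients; significance is declared at `alpha` on the adjusted
#' p-values. `"Healthy"` is used as the reference cohort when present.
#' Singular fits are reported via the `singular` attribute, not raised.
#'
#' @param scores per-visit data frame: `subject_id`, `visit`, `score`.
#' @param clinical clinical table with `subject_id`, `cohort`, `age`.
#' @param alpha significance level on BH-adjusted p-values (default 0.01).
#' @return data frame with one row per fixed effect: `term`, `estimate`,
#'   `se`, `z`, `p`, `p_adj` (`NA` for the intercept), `significant`;
#'   attributes `fit` (the `lmerMod`), `singular`, `alpha`.
#' @export
age_mixed_model <- function(scores, clinical, alpha = 0.01) {
  stopifnot(all(c("subject_id", "score") %in% names(scores)))
  d <- merge(scores, clinical[, c("subject_id", "cohort", "age")],
             by = "subject_id")
  if (length(unique(d$cohort)) < 2L)
    stop("need at least 2 cohorts", call. = FALSE)
  levs <- unique(d$cohort)
  if ("Healthy" %in% levs) levs <- c("Healthy", setdiff(levs, "Healthy"))
  d$cohort <- factor(d$cohort, levels = levs)
  fit <- lme4::lmer(score ~ age * cohort + (1 | subject_id), data = d,
                    control = lme4::lmerControl(check.conv.singular =
                      lme4::.makeCC(action = "ignore", tol = 1e-4)))
  singular <- lme4::isSingular(fit)
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- data.frame(term = names(est), estimate = unname(est),
                    se = unname(se), z = unname(z), p = unname(p),
                    stringsAsFactors = FALSE)
  rep_idx <- tab$term != "(Intercept)"
  tab$p_adj <- NA_real_
  tab$p_adj[rep_idx] <- stats::p.adjust(tab$p[rep_idx], method = "BH")
  tab$significant <- !is.na(tab$p_adj) & tab$p_adj < alpha
  attr(tab, "fit") <- fit
  attr(tab, "singular") <- singular
  attr(tab, "alpha") <- alpha
  tab
}

#' Compare the aligned shape-PCA index against unaligned baselines
#'
#' Runs the identical bootstrapped-PLS harness on three feature sets derived
#' from the same raw curves: (a) shape PCA after elastic alignment, (b)
#' functional PCA of the unaligned curves (`stats::prcomp`), and (c)
#' non-negative matrix factorization of the unaligned, non-negatively
#' shifted curves. Each method contributes its first two scores per
#' activity; the same bootstrap seed is used for all methods so replicates
#' are paired. When curves carry no phase variability the aligned and
#' unaligned decompositions should perform alike; under strong phase
#' variability alignment protects the speed mode and the aligned index's
#' first-component median is expected to be the largest.
#'
#' @param curves list of [trajectory()] objects (one repetition per subject
#'   and activity; with several visits the lowest visit number is used).
#' @param clinical clinical table (see [pearson_panel()]).
#' @param n_boot,train_frac,seed passed to [bootstrap_pls()].
#' @param n_components PLS components per method (default 3, truncated to
#'   the block dimensions).
#' @param y_vars clinical variables forming the Y block.
#' @param tol,max_iter passed to [karcher_mean()].
#' @return data frame: `method`, `component`, `median`, `q05`, `q95`,
#'   `n_skipped`.
#' @export
baseline_comparison <- function(curves, clinical, n_boot = 1000L,
                                train_frac = 0.7, seed, n_components = 3L,
                                y_vars = c("age", "avg_echo", "net", "brooke"),
                                tol = 5e-3, max_iter = 20L) {
  info <- data.frame(
    idx = seq_along(curves),
    subject_id = vapply(curves, `[[`, "", "subject_id"),
    visit = vapply(curves, `[[`, 0L, "visit"),
    activity = vapply(curves, `[[`, "", "activity"),
    stringsAsFactors = FALSE)
  activities <- sort(unique(info$activity))
  subjects <- sort(unique(info$subject_id))
  subjects <- subjects[vapply(subjects, function(s)
    all(activities %in% info$activity[info$subject_id == s]), TRUE)]
  pick_one <- function(act) {
    vapply(subjects, function(s) {
      cand <- info[info$subject_id == s & info$activity == act, ]
      cand$idx[which.min(cand$visit)]
    }, 0L)
  }
  n_grid <- length(curves[[1L]]$grid)

  feats <- list(shape = NULL, fpca = NULL, nmf = NULL)
  for (act in activities) {
    sel <- curves[pick_one(act)]
    cols <- paste0(c("VPC1_", "VPC2_"), act)
    # (a) aligned shape PCA
    sep <- separate_phase_amplitude(sel, tol = tol, max_iter = max_iter)
    pca <- fit_shape_pca(sep, n_retained = 2L)
    sc <- pca$scores[, 1:2, drop = FALSE]; colnames(sc) <- cols
    feats$shape <- cbind(feats$shape, sc)
    # (b) unaligned functional PCA
    V <- t(vapply(sel, `[[`, numeric(n_grid), "values"))
    pc <- stats::prcomp(V, center = TRUE, scale. = FALSE)
    sc <- pc$x[, 1:2, drop = FALSE]; colnames(sc) <- cols
    feats$fpca <- cbind(feats$fpca, sc)
    # (c) NMF on the non-negatively shifted curves
    sc <- nmf_scores(V - min(V), rank = 2L, seed = seed + 17L)
    colnames(sc) <- cols
    feats$nmf <- cbind(feats$nmf, sc)
  }

  ord <- match(subjects, clinical$subject_id)
  Y <- as.matrix(clinical[ord, y_vars, drop = FALSE])
  out <- list()
  for (m in names(feats)) {
    bi <- suppressWarnings(
      bootstrap_pls(feats[[m]], Y, n_boot = n_boot, train_frac = train_frac,
                    seed = seed, n_components = n_components))
    out[[m]] <- data.frame(method = m,
                           component = seq_along(bi$median),
                           median = unname(bi$median),
                           q05 = unname(bi$ci90["lower", ]),
                           q95 = unname(bi$ci90["upper", ]),
                           n_skipped = bi$n_skipped,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# Lee-Seung multiplicative-update NMF (Frobenius loss). Written in-package
# because the analysis only needs scores of a small rank-2 factorization;
# seeded uniform initialization makes it deterministic. Components are
# ordered by decreasing energy.
nmf_scores <- function(V, rank = 2L, seed = 1L, n_iter = 300L) {
  stopifnot(all(V >= 0))
  n <- nrow(V); m <- ncol(V)
  eps <- 1e-9
  with_seed(seed, {
    W <- matrix(stats::runif(n * rank, 0.1, 1), n, rank)
    H <- matrix(stats::runif(rank * m, 0.1, 1), rank, m)
  })
  for (it in seq_len(n_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
  }
  energy <- vapply(seq_len(rank), function(k)
    sum(W[, k]^2) * sum(H[k, ]^2), 0)
  W[, order(energy, decreasing = TRUE), drop = FALSE]
}
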