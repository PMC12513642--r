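# Readers/writers and end-to-end pipeline orchestration.

#' Write trajectories to a long CSV
#'
#' One row per sample, columns `subject_id`, `visit`, `activity`, `t`,
#' `gyro_y`; one repetition per (subject_id, visit, activity) group.
#'
#' @param curves list of [trajectory()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(curves, path) {
  rows <- lapply(curves, function(b) {
    data.frame(subject_id = b$subject_id, visit = b$visit,
               activity = b$activity, t = b$grid, gyro_y = b$values,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read trajectories from a long CSV
#'
#' Reads the dialect written by [write_trajectories()] (header required:
#' `subject_id`, `visit`, `activity`, `t`, `gyro_y`), groups rows into
#' repetitions by (subject_id, visit, activity), validates each repetition
#' (finite values, strictly increasing time, at least 8 samples) and
#' resamples it onto a common uniform unit-interval grid. Malformed rows
#' (non-numeric `t`/`gyro_y`) raise an error naming the offending line
#' numbers; repetitions with non-monotone time or too few samples are
#' rejected with a warning naming the repetition and are not returned.
#'
#' @param path CSV path.
#' @param n_grid common grid length after resampling (default 200).
#' @return list of [trajectory()] objects; attribute `n_rejected` counts
#'   rejected repetitions.
#' @export
read_trajectories <- function(path, n_grid = 200L) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "visit", "activity", "t", "gyro_y")
  if (!all(need %in% names(d)))
    stop("missing required columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(suppressWarnings(as.numeric(d$t))) |
                 !is.finite(suppressWarnings(as.numeric(d$gyro_y))))
  if (length(bad))
    stop("malformed rows at line(s): ",
         paste(utils::head(bad + 1L, 20L), collapse = ", "), call. = FALSE)
  key <- paste(d$subject_id, d$visit, d$activity, sep = "/")
  out <- list()
  n_rejected <- 0L
  for (k in unique(key)) {
    g <- d[key == k, ]
    if (any(diff(g$t) <= 0)) {
      warning(sprintf("repetition %s rejected: time not strictly increasing", k))
      n_rejected <- n_rejected + 1L
      next
    }
    if (nrow(g) < 8L) {
      warning(sprintf("repetition %s rejected: fewer than 8 samples", k))
      n_rejected <- n_rejected + 1L
      next
    }
    b <- trajectory(g$gyro_y, g$t - g$t[1L], subject_id = g$subject_id[1L],
                    visit = g$visit[1L], activity = g$activity[1L])
    out[[length(out) + 1L]] <- resample_trajectory(b, n_grid = n_grid)
  }
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Pipeline configuration
#'
#' Bundles paths (or in-memory objects) and stage parameters for
#' [run_pipeline()]. `trajectories` and `clinical` may be CSV paths or the
#' corresponding objects. A single mandatory top-level `seed` is split
#' deterministically into per-stage seeds (recorded in the manifest), so one
#' knob reproduces the whole run.
#'
#' @param trajectories CSV path or list of [trajectory()] objects.
#' @param clinical CSV path or clinical data frame.
#' @param out_dir output directory.
#' @param seed integer seed (mandatory).
#' @param n_grid common grid length.
#' @param pre_smooth smooth each curve with [smooth_trajectory()] before
#'   analysis (default `TRUE`; differentiation inside the SRVF transform
#'   amplifies sensor noise).
#' @param tol,max_iter,center_phase Karcher-mean controls.
#' @param n_retained VPCs retained for reporting (the index always uses
#'   VPC1/VPC2 per activity).
#' @param n_runs random-visit shape-PCA repetitions.
#' @param refit refit alignment per run (see [repeated_shape_pca()]).
#' @param n_boot,train_frac bootstrap controls.
#' @param y_vars clinical variables in the PLS Y block.
#' @param patient_cohorts cohorts entering the PLS index (Healthy is
#'   excluded by default because Brooke is not collected for it).
#' @param run_baselines run the decomposition baseline comparison.
#' @param make_plots write PNG diagnostic plots.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(trajectories, clinical, out_dir, seed,
                            n_grid = 200L, pre_smooth = TRUE,
                            tol = 5e-3, max_iter = 20L,
                            center_phase = TRUE, n_retained = 3L,
                            n_runs = 100L, refit = TRUE,
                            n_boot = 10000L, train_frac = 0.7,
                            y_vars = c("age", "avg_echo", "net", "brooke"),
                            patient_cohorts = c("DMD", "SMA"),
                            run_baselines = TRUE, make_plots = FALSE) {
  stopifnot(!missing(seed), is.finite(seed))
  stopifnot(train_frac > 0, train_frac < 1, n_runs >= 1L, n_boot >= 1L)
  structure(list(trajectories = trajectories, clinical = clinical,
                 out_dir = out_dir, seed = as.integer(seed),
                 n_grid = as.integer(n_grid), pre_smooth = pre_smooth,
                 tol = tol,
                 max_iter = as.integer(max_iter),
                 center_phase = center_phase,
                 n_retained = as.integer(n_retained),
                 n_runs = as.integer(n_runs), refit = refit,
                 n_boot = as.integer(n_boot), train_frac = train_frac,
                 y_vars = y_vars, patient_cohorts = patient_cohorts,
                 run_baselines = run_baselines, make_plots = make_plots),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Reads a config file whose keys match the arguments of
#' [pipeline_config()] and validates it.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

#' Run the full shape-analysis pipeline
#'
#' Executes, in order: trajectory loading, per-activity phase-amplitude
#' separation, shape PCA, the repeated random-visit embedding, the
#' bootstrapped PLS index on the patient cohorts, the per-cohort Pearson
#' panel, the age-by-cohort mixed model on per-visit VPC1 scores of the
#' first activity, and (optionally) the decomposition baseline comparison.
#' All stage outputs are written as CSV/JSON under `out_dir` together with a
#' manifest (parameters, per-stage seeds, warning log, artifact list). With
#' a fixed config the manifests and artifacts of two runs are identical.
#'
#' @param config a [pipeline_config()] or path to one (YAML/JSON).
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_warnings <- character()
  note <- function(...) {
    log_warnings <<- c(log_warnings, sprintf(...))
  }
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      note("%s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  stage_seeds <- cfg$seed + c(embedding = 1L, index = 2L, baseline = 3L)

  curves <- if (is.character(cfg$trajectories))
    collect(read_trajectories(cfg$trajectories, n_grid = cfg$n_grid))
  else cfg$trajectories
  clinical <- if (is.character(cfg$clinical)) {
    if (!file.exists(cfg$clinical))
      stop(sprintf("stage 'index': clinical file not found: %s", cfg$clinical),
           call. = FALSE)
    utils::read.csv(cfg$clinical, stringsAsFactors = FALSE)
  } else cfg$clinical

  if (isTRUE(cfg$pre_smooth)) curves <- lapply(curves, smooth_trajectory)

  activities <- sort(unique(vapply(curves, `[[`, "", "activity")))
  separations <- list(); pcas <- list(); visit_scores <- list()
  for (act in activities) {
    sel <- which(vapply(curves, `[[`, "", "activity") == act)
    sep <- collect(separate_phase_amplitude(curves[sel], tol = cfg$tol,
                                            max_iter = cfg$max_iter,
                                            center_phase = cfg$center_phase))
    pca <- collect(fit_shape_pca(sep, n_retained = cfg$n_retained))
    separations[[act]] <- sep
    pcas[[act]] <- pca
    write_separation(sep, file.path(cfg$out_dir, paste0("separation_", act)))
    write_shape_pca(pca, file.path(cfg$out_dir, paste0("shape_pca_", act)))
    visit_scores[[act]] <- data.frame(
      subject_id = vapply(curves[sel], `[[`, "", "subject_id"),
      visit = vapply(curves[sel], `[[`, 0L, "visit"),
      activity = act, pca$scores, check.names = FALSE,
      stringsAsFactors = FALSE)
  }

  embedding <- collect(
    repeated_shape_pca(curves, n_runs = cfg$n_runs,
                       seed = stage_seeds[["embedding"]],
                       n_retained = 2L, refit = cfg$refit,
                       tol = cfg$tol, max_iter = cfg$max_iter))
  utils::write.csv(embedding, file.path(cfg$out_dir, "embedding.csv"),
                   row.names = FALSE)

  feats <- attr(embedding, "features")
  pat <- clinical$subject_id[clinical$cohort %in% cfg$patient_cohorts]
  rows <- embedding$subject_id %in% pat
  ord <- match(embedding$subject_id[rows], clinical$subject_id)
  X <- as.matrix(embedding[rows, feats, drop = FALSE])
  Y <- as.matrix(clinical[ord, cfg$y_vars, drop = FALSE])
  index <- collect(bootstrap_pls(X, Y, n_boot = cfg$n_boot,
                                 train_frac = cfg$train_frac,
                                 seed = stage_seeds[["index"]],
                                 n_components = min(ncol(X), ncol(Y))))
  jsonlite::write_json(
    list(median = as.list(stats::setNames(index$median,
                                          paste0("component", seq_along(index$median)))),
         ci_5_95 = list(lower = unname(index$ci90["lower", ]),
                        upper = unname(index$ci90["upper", ])),
         ci_2.5_97.5 = list(lower = unname(index$ci95["lower", ]),
                            upper = unname(index$ci95["upper", ])),
         x_weights = as.list(coef(index)),
         n_boot = index$n_boot, n_skipped = index$n_skipped,
         n_subjects = index$n),
    file.path(cfg$out_dir, "index.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(replicate = seq_len(cfg$n_boot), index$boot_cor,
               check.names = FALSE),
    file.path(cfg$out_dir, "bootstrap_correlations.csv"), row.names = FALSE)

  panel <- pearson_panel(embedding, clinical, features = feats)
  utils::write.csv(panel, file.path(cfg$out_dir, "correlations.csv"),
                   row.names = FALSE)

  sc1 <- visit_scores[[activities[1L]]]
  mm <- collect(age_mixed_model(
    data.frame(subject_id = sc1$subject_id, visit = sc1$visit,
               score = sc1[["VPC1"]], stringsAsFactors = FALSE),
    clinical))
  utils::write.csv(as.data.frame(mm), file.path(cfg$out_dir, "mixed_model.csv"),
                   row.names = FALSE)

  baselines <- NULL
  if (cfg$run_baselines) {
    yb <- cfg$y_vars
    clin_b <- clinical[clinical$cohort %in% cfg$patient_cohorts, ]
    curves_b <- curves[vapply(curves, `[[`, "", "subject_id") %in%
                         clin_b$subject_id]
    baselines <- collect(baseline_comparison(
      curves_b, clin_b, n_boot = min(cfg$n_boot, 2000L),
      train_frac = cfg$train_frac, seed = stage_seeds[["baseline"]],
      n_components = min(4L, length(yb)), y_vars = yb,
      tol = cfg$tol, max_iter = cfg$max_iter))
    utils::write.csv(baselines, file.path(cfg$out_dir, "baselines.csv"),
                     row.names = FALSE)
  }

  if (cfg$make_plots) {
    grDevices::png(file.path(cfg$out_dir, "modes_%d.png"), width = 900,
                   height = 500)
    for (act in activities) plot(pcas[[act]], k = 1L)
    grDevices::dev.off()
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("motorshape")),
    seed = cfg$seed, stage_seeds = as.list(stage_seeds),
    parameters = cfg[c("n_grid", "pre_smooth", "tol", "max_iter", "center_phase",
                       "n_retained", "n_runs", "refit", "n_boot",
                       "train_frac", "y_vars", "patient_cohorts")],
    n_curves = length(curves), activities = activities,
    n_subjects = length(unique(vapply(curves, `[[`, "", "subject_id"))),
    warnings = log_warnings,
    artifacts = list.files(cfg$out_dir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(separations = separations, shape_pca = pcas,
                 embedding = embedding, index = index, panel = panel,
                 mixed_model = mm, baselines = baselines,
                 manifest = manifest))
}
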