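#' Configuration for an end-to-end synthetic pipeline run
#'
#' Collects every knob of the simulate -> build-models -> fit ->
#' partition -> infer pipeline with reproducible seeds. Defaults give a
#' desk-scale study: 24 images in the standard category proportions,
#' 10 participants, 2 ms sampling from -100 to 198 ms, moderate pair
#' noise, and a planted early-network / late-semantic reversal across
#' two pseudo-ROIs.
#'
#' @param n_images stimulus-set size.
#' @param n_participants simulated participants per pseudo-ROI.
#' @param times_ms time axis (ms; must include a prestimulus window).
#' @param noise_sd pair-noise standard deviation.
#' @param dnn_onset_ms,semantic_onset_ms planted onsets.
#' @param grid ridge penalty grid for first-level fitting.
#' @param inner_folds inner image folds for penalty selection.
#' @param test_size,composition outer-fold test-set stratification.
#' @param max_folds fold-schedule cap.
#' @param q FDR level; `min_run` continuity criterion (samples).
#' @param min_run minimum significant run length.
#' @param n_units units per synthetic network layer.
#' @param observer_noise labeling-experiment reliability (0 = perfect).
#' @param seed master seed; all stage seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(n_images = 24L, n_participants = 10L,
                       times_ms = seq(-100, 198, by = 2),
                       noise_sd = 0.3, dnn_onset_ms = 60,
                       semantic_onset_ms = 140,
                       grid = lambda_grid(5L, c(1e-3, 1e1)),
                       inner_folds = 3L, test_size = 8L,
                       composition = c(faces = 2L, bodyparts = 2L,
                                       inanimate = 4L),
                       max_folds = 3000L, q = 0.05, min_run = 10L,
                       n_units = 40L, observer_noise = 0.15,
                       seed = 1L) {
  cfg <- list(n_images = n_images, n_participants = n_participants,
              times_ms = times_ms, noise_sd = noise_sd,
              dnn_onset_ms = dnn_onset_ms,
              semantic_onset_ms = semantic_onset_ms, grid = grid,
              inner_folds = inner_folds, test_size = test_size,
              composition = composition, max_folds = max_folds,
              q = q, min_run = min_run, n_units = n_units,
              observer_noise = observer_noise, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Build the full predictor set for a configuration
#'
#' Simulates layer activations (feedforward spec) and a labeling
#' experiment, runs the label pipeline (generation threshold,
#' validation agreement, correlated-dimension merging), and combines
#' network-layer and visuo-semantic predictors over the configured
#' stimulus set.
#'
#' @param cfg a [run_config()].
#' @return List with `stimuli`, `predictors` (a [predictor_set()]),
#'   `feature_matrix`, and `activations`.
#' @export
build_model_predictors <- function(cfg) {
  stimuli <- synth_stimuli(scaled_counts(cfg$n_images))
  acts <- generate_activations(layer_spec("feedforward"), stimuli,
                               n_units = cfg$n_units,
                               seed = cfg$seed + 11L)
  dnn <- predictors_from_activations(acts, submodel = "feedforward")
  lab <- generate_label_experiment(stimuli,
                                   observer_noise = cfg$observer_noise,
                                   seed = cfg$seed + 23L)
  kept <- select_generated_labels(lab$gen)
  fm <- validate_labels(lab$val, labels = kept, dim_group = lab$dim_group)
  fm <- merge_correlated_dimensions(fm)
  sem <- group_submodels(fm)
  list(stimuli = stimuli, predictors = combine_predictors(dnn, sem),
       feature_matrix = fm, activations = acts)
}

#' First-level predictions for every participant and model class
#'
#' Runs [crossval_predict_movie()] per participant and model class on
#' a shared fold schedule.
#'
#' @param movies list of [rdm_movie()] (one per participant).
#' @param predictors combined [predictor_set()].
#' @param stimuli the [stimulus_set()].
#' @param cfg a [run_config()].
#' @param classes model classes to fit (default both).
#' @return List (per participant) of named lists (per class) of
#'   `crossval_prediction` objects.
#' @export
first_level_by_class <- function(movies, predictors, stimuli, cfg,
                                 classes = c("dnn", "visuo_semantic")) {
  schedule <- fold_schedule(stimuli, seed = cfg$seed + 101L,
                            max_folds = cfg$max_folds,
                            test_size = cfg$test_size,
                            composition = cfg$composition)
  lapply(movies, function(mv) {
    stats::setNames(lapply(classes, function(cl) {
      crossval_predict_movie(mv, subset_predictors(predictors, cl),
                             schedule, grid = cfg$grid,
                             inner_folds = cfg$inner_folds,
                             seed = cfg$seed + 211L, stimuli = stimuli)
    }), classes)
  })
}

#' Run the full synthetic pipeline
#'
#' Simulate the reversal scenario, fit both model classes per
#' participant/ROI/time with cross-validated nonnegative ridge
#' regression, partition variance with nonnegative GLMs, and run
#' group inference. Bit-reproducible given the config seed.
#'
#' @param cfg a [run_config()].
#' @param out_dir optional directory; when given, tidy CSV tables and
#'   a JSON report are written there.
#' @return List with `config`, `truth`, `timecourses` (per ROI),
#'   `inference` (per ROI x measure), and `report` (onsets and
#'   significant windows).
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = NULL) {
  models <- build_model_predictors(cfg)
  scen <- make_reversal_scenario(models$predictors, cfg$times_ms,
                                 seed = cfg$seed + 307L,
                                 noise_sd = cfg$noise_sd,
                                 n_participants = cfg$n_participants,
                                 dnn_onset_ms = cfg$dnn_onset_ms,
                                 semantic_onset_ms = cfg$semantic_onset_ms)
  tcs <- list(); inf <- list(); rows <- list()
  for (roi in c("roi1", "roi2")) {
    movies <- scen[[roi]]
    preds <- first_level_by_class(movies, models$predictors,
                                  models$stimuli, cfg)
    tc <- partition_group(movies, preds)
    tcs[[roi]] <- tc
    for (ms in grep("^(total|unique)\\.", names(tc), value = TRUE)) {
      res <- infer_timecourse(tc[[ms]],
                              baseline = c(min(cfg$times_ms), 0),
                              alternative = "greater", q = cfg$q,
                              min_run = cfg$min_run)
      inf[[paste(roi, ms, sep = ".")]] <- res
      win <- significant_windows(res)
      rows[[paste(roi, ms, sep = ".")]] <- data.frame(
        roi = roi, measure = res$measure, model = res$model,
        onset_ms = res$onset_ms, n_windows = nrow(win),
        windows = paste(sprintf("[%g,%g]", win$start_ms, win$end_ms),
                        collapse = " "))
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  out <- list(config = cfg, truth = scen$truth, timecourses = tcs,
              inference = inf, report = report)
  if (!is.null(out_dir)) .write_pipeline_outputs(out, out_dir)
  out
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

.write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(out$config)
  tidy <- do.call(rbind, lapply(names(out$timecourses), function(roi) {
    do.call(rbind, lapply(out$timecourses[[roi]], function(tc) {
      if (!inherits(tc, "time_course")) return(NULL)
      data.frame(participant = rep(rownames(tc$values),
                                   times = ncol(tc$values)),
                 roi = roi, measure = tc$measure, model = tc$model,
                 time_ms = rep(tc$times_ms, each = nrow(tc$values)),
                 value = as.vector(tc$values))
    }))
  }))
  utils::write.csv(tidy, file.path(out_dir, "timecourses.csv"),
                   row.names = FALSE)
  utils::write.csv(out$report, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = hash, seed = out$config$seed,
         report = out$report),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(out_dir)
}

#' Diagnostics on pipeline inputs
#'
#' Checks id alignment between movies and predictors, flags
#' zero-variance predictor columns and movie frames, and verifies that
#' the fold composition is feasible for the stimulus set. Reports
#' only; never throws.
#'
#' @param movies list of [rdm_movie()] objects.
#' @param predictors a [predictor_set()].
#' @param stimuli a [stimulus_set()].
#' @param composition test-set composition to check.
#' @return data.frame with columns `check`, `item`, `message` (zero
#'   rows when everything is clean).
#' @export
validate_inputs <- function(movies, predictors, stimuli,
                            composition = c(faces = 2L, bodyparts = 2L,
                                            inanimate = 4L)) {
  rows <- list()
  flag <- function(check, item, message) {
    rows[[length(rows) + 1]] <<- data.frame(check = check, item = item,
                                            message = message)
  }
  for (mv in movies) {
    if (!identical(mv$condition_ids, predictors$condition_ids))
      flag("condition_ids", mv$participant_id,
           "movie and predictor condition ids differ")
    zv <- apply(mv$frames, 2, stats::sd) == 0
    if (any(zv))
      flag("zero_variance_frame", mv$participant_id,
           paste("frames:", paste(which(zv), collapse = ",")))
  }
  zv <- apply(predictors$X, 2, stats::sd) == 0
  if (any(zv))
    flag("zero_variance_predictor",
         paste(predictors$names[zv], collapse = ","),
         "predictor RDM has no pair variance")
  strata <- .fold_strata(stimuli)
  for (s in names(composition)) {
    if (length(strata[[s]]) < composition[[s]])
      flag("composition", s,
           sprintf("need %d, have %d", composition[[s]],
                   length(strata[[s]])))
  }
  if (length(rows) == 0)
    data.frame(check = character(), item = character(),
               message = character())
  else do.call(rbind, rows)
}
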