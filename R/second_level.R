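#' Total explained variance of one model's cross-validated prediction
#'
#' Fits the model's prediction vector (plus intercept) to the data with
#' nonnegative least squares — the "reduced GLM" containing a single
#' model class — and returns the regression R^2.
#'
#' @param y observed dissimilarity vector at one time point.
#' @param prediction cross-validated prediction vector for one model
#'   class (or a `crossval_prediction` object).
#' @return R^2 (scalar; may be negative, never clipped).
#' @export
total_variance <- function(y, prediction) {
  v <- if (inherits(prediction, "crossval_prediction")) prediction$v_hat
       else prediction
  nnls_glm(y, cbind(pred = as.numeric(v)))$r2
}

#' Unique explained variance of each model class
#'
#' Fits the full nonnegative GLM (all prediction vectors + intercept)
#' and, for each class, a reduced GLM omitting that class; the unique
#' variance of a class is `r2(full) - r2(without that class)`. Because
#' the feasible sets nest, the full fit can never do worse than a
#' reduced fit beyond solver tolerance, so unique variance is
#' nonnegative up to that tolerance.
#'
#' @param y observed dissimilarity vector at one time point.
#' @param predictions named list of prediction vectors, one per model
#'   (e.g. `list(dnn = ..., visuo_semantic = ...)`).
#' @return List with `full_r2`, `total` (per-model reduced-GLM R^2)
#'   and `unique` (per-model unique variance).
#' @export
unique_variance <- function(y, predictions) {
  stopifnot(is.list(predictions), length(predictions) >= 2,
            !is.null(names(predictions)))
  predictions <- lapply(predictions, function(p) {
    if (inherits(p, "crossval_prediction")) p$v_hat else as.numeric(p)
  })
  Xfull <- do.call(cbind, predictions)
  full <- nnls_glm(y, Xfull)$r2
  tot <- vapply(predictions, function(p) nnls_glm(y, cbind(p))$r2, 0)
  uniq <- vapply(names(predictions), function(m) {
    full - nnls_glm(y, Xfull[, setdiff(names(predictions), m),
                             drop = FALSE])$r2
  }, 0)
  list(full_r2 = full, total = tot, unique = uniq)
}

#' Per-participant time course of a variance measure
#'
#' @param times_ms frame times.
#' @param values participants x time matrix.
#' @param measure label, e.g. `"total_r2"` or `"unique_r2"`.
#' @param model model/submodel name the measure refers to.
#' @param roi_id region label.
#' @return A `time_course` object.
#' @export
time_course <- function(times_ms, values, measure, model, roi_id = "roi") {
  values <- as.matrix(values)
  if (ncol(values) != length(times_ms))
    stop("values must have one column per time point")
  structure(list(times_ms = times_ms, values = values, measure = measure,
                 model = model, roi_id = roi_id),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course> %s(%s) @ %s: %d participants x %d times\n",
              x$measure, x$model, x$roi_id, nrow(x$values),
              ncol(x$values)))
  invisible(x)
}

#' Variance partitioning over an RDM movie
#'
#' For one participant's movie and per-class cross-validated prediction
#' movies, computes at every time point the full-GLM R^2, each class's
#' total (reduced-GLM) R^2 and each class's unique variance.
#'
#' @param movie an [rdm_movie()].
#' @param predictions named list of `crossval_prediction` objects from
#'   [crossval_predict_movie()] (or pairs x time matrices), one per
#'   model class/submodel, sharing the movie's time axis.
#' @return List of per-measure time x 1 matrices: `full_r2`, and per
#'   model `total.<name>` and `unique.<name>` numeric vectors over
#'   time.
#' @export
partition_movie <- function(movie, predictions) {
  stopifnot(inherits(movie, "rdm_movie"))
  mats <- lapply(predictions, function(p) {
    m <- if (inherits(p, "crossval_prediction")) p$v_hat else as.matrix(p)
    if (!is.null(attr(p, "times_ms")) &&
        !isTRUE(all.equal(attr(p, "times_ms"), movie$times_ms)))
      stop("prediction and movie time axes differ")
    if (inherits(p, "crossval_prediction") && !is.null(p$times_ms) &&
        !isTRUE(all.equal(p$times_ms, movie$times_ms)))
      stop("prediction and movie time axes differ")
    if (ncol(m) != length(movie$times_ms))
      stop("prediction and movie time axes differ")
    m
  })
  TT <- length(movie$times_ms)
  nm <- names(mats)
  out <- list(full_r2 = numeric(TT))
  for (m in nm) {
    out[[paste0("total.", m)]] <- numeric(TT)
    out[[paste0("unique.", m)]] <- numeric(TT)
  }
  for (t in seq_len(TT)) {
    uv <- unique_variance(movie$frames[, t],
                          stats::setNames(lapply(mats, function(m) m[, t]),
                                          nm))
    out$full_r2[t] <- uv$full_r2
    for (m in nm) {
      out[[paste0("total.", m)]][t] <- uv$total[[m]]
      out[[paste0("unique.", m)]][t] <- uv$unique[[m]]
    }
  }
  out
}

#' Group-level variance-partitioning time courses
#'
#' Runs [partition_movie()] for every participant of one ROI and
#' assembles [time_course()] objects per measure and model.
#'
#' @param movies list of [rdm_movie()] objects, one per participant,
#'   sharing time axis and ROI.
#' @param predictions_by_participant list (one element per participant)
#'   of named lists of predictions as in [partition_movie()].
#' @return Named list of [time_course()] objects: `total.<model>` and
#'   `unique.<model>` for every model, plus `full_r2`.
#' @export
partition_group <- function(movies, predictions_by_participant) {
  stopifnot(length(movies) == length(predictions_by_participant))
  per <- Map(partition_movie, movies, predictions_by_participant)
  times <- movies[[1]]$times_ms
  roi <- movies[[1]]$roi_id
  measures <- names(per[[1]])
  out <- lapply(measures, function(ms) {
    vals <- do.call(rbind, lapply(per, `[[`, ms))
    rownames(vals) <- vapply(movies, `[[`, "", "participant_id")
    model <- sub("^(total|unique)\\.", "", ms)
    kind <- if (startsWith(ms, "unique")) "unique_r2"
            else if (startsWith(ms, "total")) "total_r2" else "full_r2"
    time_course(times, vals, kind, model, roi)
  })
  stats::setNames(out, measures)
}
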