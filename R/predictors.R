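#' Predictor sets: named model RDMs for regression
#'
#' A predictor set collects vectorised model RDMs over a common
#' condition set, tagged with a model class (`dnn` or `visuo_semantic`)
#' and a submodel (the dimension group for visuo-semantic predictors,
#' the architecture for network layers).
#'
#' @param X pairs x n_predictors numeric matrix of vectorised RDMs
#'   (canonical pair order; colnames are predictor names).
#' @param condition_ids character vector of condition identifiers.
#' @param model_class character vector (`"dnn"` or `"visuo_semantic"`),
#'   one per predictor.
#' @param submodel character vector, one per predictor.
#' @return A `predictor_set` object.
#' @export
predictor_set <- function(X, condition_ids, model_class, submodel) {
  X <- as.matrix(X)
  n <- length(condition_ids)
  if (nrow(X) != n * (n - 1) / 2)
    stop("X must have one row per condition pair")
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("pred%03d", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X))) stop("predictor names must be unique")
  model_class <- rep_len(as.character(model_class), ncol(X))
  submodel <- rep_len(as.character(submodel), ncol(X))
  if (!all(model_class %in% c("dnn", "visuo_semantic")))
    stop("model_class must be 'dnn' or 'visuo_semantic'")
  structure(list(X = X, condition_ids = as.character(condition_ids),
                 names = colnames(X),
                 model_class = stats::setNames(model_class, colnames(X)),
                 submodel = stats::setNames(submodel, colnames(X))),
            class = "predictor_set")
}

#' @export
print.predictor_set <- function(x, ...) {
  tab <- table(x$model_class)
  cat(sprintf("<predictor_set> %d predictors over %d conditions (%s)\n",
              ncol(x$X), length(x$condition_ids),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Combine predictor sets over the same conditions
#'
#' @param ... `predictor_set` objects sharing condition ids.
#' @return A single [predictor_set()].
#' @export
combine_predictors <- function(...) {
  sets <- list(...)
  ids <- sets[[1]]$condition_ids
  for (s in sets) {
    stopifnot(inherits(s, "predictor_set"))
    if (!identical(s$condition_ids, ids))
      stop("predictor sets must share condition_ids")
  }
  predictor_set(do.call(cbind, lapply(sets, `[[`, "X")), ids,
                unlist(lapply(sets, `[[`, "model_class")),
                unlist(lapply(sets, `[[`, "submodel")))
}

#' Subset a predictor set
#'
#' @param pset a [predictor_set()].
#' @param model_class,submodel optional filters; keep predictors whose
#'   tag is among the given values.
#' @param names optional character vector of predictor names to keep.
#' @return A [predictor_set()].
#' @export
subset_predictors <- function(pset, model_class = NULL, submodel = NULL,
                              names = NULL) {
  keep <- rep(TRUE, ncol(pset$X))
  if (!is.null(model_class)) keep <- keep & pset$model_class %in% model_class
  if (!is.null(submodel)) keep <- keep & pset$submodel %in% submodel
  if (!is.null(names)) keep <- keep & pset$names %in% names
  if (!any(keep)) stop("no predictors match the filter")
  predictor_set(pset$X[, keep, drop = FALSE], pset$condition_ids,
                pset$model_class[keep], pset$submodel[keep])
}

#' Build per-dimension predictors from a feature matrix
#'
#' One squared-difference RDM per dimension, tagged
#' `model_class = "visuo_semantic"` and `submodel = dim_group`.
#'
#' @param fm a [feature_matrix()].
#' @return A [predictor_set()].
#' @export
group_submodels <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (any(is.na(fm$dim_group)) || any(fm$dim_group == ""))
    stop("every dimension needs a group tag")
  ids <- rownames(fm$values)
  cols <- lapply(seq_len(ncol(fm$values)), function(k) {
    vectorize(rdm_from_dimension(stats::setNames(fm$values[, k], ids)))$v
  })
  X <- do.call(cbind, cols)
  colnames(X) <- fm$dim_names
  predictor_set(X, ids, "visuo_semantic", fm$dim_group)
}

#' Build per-layer predictors from activation matrices
#'
#' One correlation-distance (1 minus Spearman) RDM per network layer.
#'
#' @param activations named list of n_images x n_units matrices, one
#'   per layer, in depth order; rownames are image ids.
#' @param submodel tag for the set (e.g. the architecture name).
#' @return A [predictor_set()] with `model_class = "dnn"`.
#' @export
predictors_from_activations <- function(activations, submodel = "dnn") {
  stopifnot(is.list(activations), length(activations) >= 1)
  ids <- rownames(activations[[1]])
  cols <- lapply(activations, function(a) {
    vectorize(rdm_correlation_distance(a, "spearman"))$v
  })
  X <- do.call(cbind, cols)
  colnames(X) <- names(activations) %||%
    sprintf("layer%02d", seq_along(activations))
  predictor_set(X, ids, "dnn", submodel)
}
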