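#' Stratified image folds for cross-validated RDM regression
#'
#' Each cross-validation fold holds out a small test set of images with
#' a fixed category composition — by default 2 faces (human or animal),
#' 2 body parts (human body parts or animal bodies) and 4 inanimate
#' objects, i.e. 8 test images, leaving 84 of 92 images for training at
#' the full stimulus-set size. Model weights are estimated on the
#' training-image pairs and used to predict the dissimilarities among
#' the held-out images only.
#'
#' @param stimuli a [stimulus_set()].
#' @param test_size number of test images (must equal the composition
#'   total).
#' @param composition named vector `c(faces =, bodyparts =,
#'   inanimate =)` giving the test-set category composition.
#' @param seed integer seed; the fold is deterministic given the seed.
#' @return A `fold_spec`: list with `train_ids`, `test_ids`, `seed`.
#' @export
make_fold <- function(stimuli, test_size = 8L,
                      composition = c(faces = 2L, bodyparts = 2L,
                                      inanimate = 4L),
                      seed = 1L) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  if (sum(composition) != test_size)
    stop("composition must sum to test_size")
  strata <- .fold_strata(stimuli)
  for (s in names(composition)) {
    if (length(strata[[s]]) < composition[[s]])
      stop("infeasible composition: only ", length(strata[[s]]),
           " images in stratum '", s, "'")
  }
  test_ids <- local_seed(seed, {
    unlist(lapply(names(composition), function(s) {
      sample(strata[[s]], composition[[s]])
    }), use.names = FALSE)
  })
  structure(list(train_ids = setdiff(stimuli$image_id, test_ids),
                 test_ids = test_ids, seed = seed),
            class = "fold_spec")
}

.fold_strata <- function(stimuli) {
  list(faces = stimuli$image_id[stimuli$face],
       bodyparts = stimuli$image_id[stimuli$bodypart],
       inanimate = stimuli$image_id[!stimuli$animate])
}

#' Fold schedule with full pair coverage
#'
#' Draws stratified folds until every unordered image pair has appeared
#' together in at least one test set, so that a cross-validated
#' prediction exists for every pairwise dissimilarity.
#'
#' @inheritParams make_fold
#' @param max_folds abort (with the uncovered pair count) if coverage
#'   is not reached within this many folds.
#' @return List of `fold_spec` objects.
#' @export
fold_schedule <- function(stimuli, seed = 1L, max_folds = 3000L,
                          test_size = 8L,
                          composition = c(faces = 2L, bodyparts = 2L,
                                          inanimate = 4L)) {
  n <- nrow(stimuli)
  pos <- .pair_positions(stimuli$image_id)
  covered <- logical(n * (n - 1) / 2)
  schedule <- vector("list", max_folds)
  k <- 0L
  while (!all(covered)) {
    if (k >= max_folds)
      stop("coverage not reached within ", max_folds, " folds: ",
           sum(!covered), " of ", length(covered), " pairs uncovered")
    k <- k + 1L
    f <- make_fold(stimuli, test_size, composition, seed = seed + k - 1L)
    covered[.pairs_within(f$test_ids, pos)] <- TRUE
    schedule[[k]] <- f
  }
  schedule[seq_len(k)]
}

# map image-id pairs to canonical pair rows
.pair_positions <- function(ids) {
  n <- length(ids)
  list(ids = ids, n = n, index = stats::setNames(seq_len(n), ids))
}

.pairs_within <- function(subset_ids, pos) {
  idx <- sort(pos$index[subset_ids])
  if (length(idx) < 2) return(integer())
  pr <- pair_index(length(idx))
  i <- idx[pr[, 1]]; j <- idx[pr[, 2]]
  .pair_pos(i, j, pos$n)
}

.pair_pos <- function(i, j, n) {
  # row-major upper-triangle position of pair (i, j), i < j
  (i - 1) * n - i * (i - 1) / 2 + (j - i)
}

#' Select the ridge penalty by nested image-level cross-validation
#'
#' Splits the training images into inner folds (stratified when every
#' stratum is large enough, plain otherwise), fits at every grid value
#' on the inner-training pairs and scores squared error on the pairs of
#' held-out inner images. Returns the grid value with minimum mean
#' held-out error; exact ties go to the larger penalty.
#'
#' @param y training-pair dissimilarities.
#' @param X training-pair predictor columns (unstandardized; each inner
#'   fit standardizes on its own training pairs).
#' @param pair_ids two-column character matrix giving the image pair of
#'   each row of `y`/`X`.
#' @param grid nonnegative candidate penalties.
#' @param inner_folds number of inner image folds (default 5).
#' @param seed integer seed for the inner split.
#' @param stimuli optional [stimulus_set()] enabling stratified inner
#'   splits.
#' @return Selected penalty (scalar), with the per-grid mean errors as
#'   attribute `"errors"`.
#' @export
select_lambda <- function(y, X, pair_ids, grid, inner_folds = 5L,
                          seed = 1L, stimuli = NULL) {
  if (any(grid < 0)) stop("grid values must be nonnegative")
  grid <- sort(grid)
  err <- .inner_cv_errors(cbind(as.numeric(y)), as.matrix(X), pair_ids,
                          grid, inner_folds, seed, stimuli)[, 1]
  sel <- max(which(err == min(err)))
  structure(grid[sel], errors = stats::setNames(err, grid))
}

# mean held-out squared error per (grid value, time point)
# Y: train pairs x T; X: train pairs x p; pair_ids: train pairs x 2
.inner_cv_errors <- function(Y, X, pair_ids, grid, inner_folds, seed,
                             stimuli) {
  train_ids <- unique(as.vector(pair_ids))
  groups <- .inner_split(train_ids, inner_folds, seed, stimuli)
  G <- length(grid); TT <- ncol(Y)
  se <- matrix(0, G, TT)
  np <- rep(0, G)
  for (g in groups) {
    in_hold <- matrix(pair_ids %in% g, ncol = 2)
    it <- !in_hold[, 1] & !in_hold[, 2]   # both images in inner-train
    iv <- in_hold[, 1] & in_hold[, 2]     # both images held out
    if (!any(iv) || sum(it) < 2) next
    std <- .standardize(X[it, , drop = FALSE])
    if (ncol(std$X) == 0) next
    Xv <- .apply_standardization(X[iv, , drop = FALSE], std)
    Ytr <- Y[it, , drop = FALSE]
    b <- colMeans(Ytr)
    Yc <- sweep(Ytr, 2, b)
    XtX <- crossprod(std$X)
    XtY <- crossprod(std$X, Yc)
    for (gi in seq_len(G)) {
      W <- .nnls_gram(XtX + diag(grid[gi], ncol(std$X)), XtY)
      pred <- sweep(Xv %*% W, 2, b, `+`)
      se[gi, ] <- se[gi, ] + colSums((Y[iv, , drop = FALSE] - pred)^2)
    }
    np <- np + sum(iv)
  }
  if (all(np == 0)) stop("no usable inner-validation pairs")
  sweep(se, 1, np, `/`)
}

.inner_split <- function(ids, k, seed, stimuli) {
  local_seed(seed, {
    if (!is.null(stimuli)) {
      strata <- .fold_strata(stimuli)
      strata <- lapply(strata, intersect, ids)
      if (all(lengths(strata) >= k)) {
        groups <- vector("list", k)
        for (s in strata) {
          s <- sample(s)
          part <- rep_len(seq_len(k), length(s))
          for (q in seq_len(k))
            groups[[q]] <- c(groups[[q]], s[part == q])
        }
        return(groups)
      }
    }
    ids <- sample(ids)
    split(ids, rep_len(seq_len(k), length(ids)))
  })
}

.standardize <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  keep <- scl > 0
  list(X = scale(X[, keep, drop = FALSE], ctr[keep], scl[keep]),
       center = ctr, scale = scl, keep = keep)
}

.apply_standardization <- function(X, std) {
  scale(X[, std$keep, drop = FALSE], std$center[std$keep],
        std$scale[std$keep])
}

#' Cross-validated model predictions of a data RDM
#'
#' For each fold of the schedule: standardize the predictors on the
#' training pairs, select the ridge penalty by nested cross-validation
#' within the training images, fit the nonnegative ridge model, and
#' predict the dissimilarities among the held-out test images only.
#' Per pair, predictions are averaged over the folds in which the pair
#' was held out.
#'
#' @param data an `rdm_vector` (see [vectorize()]) of observed
#'   dissimilarities.
#' @param predictors a [predictor_set()] (or subset) sharing the
#'   condition ids.
#' @param schedule fold list from [fold_schedule()].
#' @param grid candidate ridge penalties (default 20 values,
#'   log-spaced over 1e-4 to 1e2).
#' @param inner_folds inner image folds for penalty selection.
#' @param seed integer seed for inner splits.
#' @param stimuli optional [stimulus_set()] for stratified inner
#'   splits.
#' @return A `crossval_prediction`: list with `v_hat` (predicted
#'   vector), `coverage` (per-pair fold count), `lambda` (per-fold
#'   selected penalty).
#' @export
crossval_predict <- function(data, predictors, schedule,
                             grid = lambda_grid(), inner_folds = 5L,
                             seed = 1L, stimuli = NULL) {
  stopifnot(inherits(data, "rdm_vector"))
  res <- .crossval_core(cbind(data$v), predictors, schedule, grid,
                        inner_folds, seed, stimuli)
  structure(list(v_hat = drop(res$v_hat), coverage = res$coverage,
                 lambda = drop(res$lambda)),
            class = "crossval_prediction")
}

#' @rdname crossval_predict
#' @param movie an [rdm_movie()]; every frame is fit with the same fold
#'   schedule, sharing the per-fold Gram matrices across time points.
#' @return For `crossval_predict_movie`: `v_hat` is a pairs x time
#'   matrix and `lambda` a folds x time matrix.
#' @export
crossval_predict_movie <- function(movie, predictors, schedule,
                                   grid = lambda_grid(),
                                   inner_folds = 5L, seed = 1L,
                                   stimuli = NULL) {
  stopifnot(inherits(movie, "rdm_movie"))
  res <- .crossval_core(movie$frames, predictors, schedule, grid,
                        inner_folds, seed, stimuli)
  structure(list(v_hat = res$v_hat, coverage = res$coverage,
                 lambda = res$lambda, times_ms = movie$times_ms),
            class = "crossval_prediction")
}

#' Default ridge penalty grid
#'
#' @param n number of grid values.
#' @param range log10 range endpoints.
#' @return Increasing numeric vector, log-spaced over `range`.
#' @export
lambda_grid <- function(n = 20L, range = c(1e-4, 1e2)) {
  10^seq(log10(range[1]), log10(range[2]), length.out = n)
}

.crossval_core <- function(Y, predictors, schedule, grid, inner_folds,
                           seed, stimuli) {
  stopifnot(inherits(predictors, "predictor_set"))
  if (any(grid < 0)) stop("grid values must be nonnegative")
  grid <- sort(grid)
  ids <- predictors$condition_ids
  X <- predictors$X
  n <- length(ids)
  npair <- n * (n - 1) / 2
  if (nrow(Y) != npair) stop("data and predictors disagree on pair count")
  pos <- .pair_positions(ids)
  pr <- pair_index(n)
  pair_ids <- cbind(ids[pr[, 1]], ids[pr[, 2]])

  TT <- ncol(Y)
  pred_sum <- matrix(0, npair, TT)
  coverage <- integer(npair)
  lambda_sel <- matrix(NA_real_, length(schedule), TT)

  for (f in seq_along(schedule)) {
    fold <- schedule[[f]]
    if (!all(c(fold$train_ids, fold$test_ids) %in% ids))
      stop("fold images missing from the predictor condition set")
    tr <- .pairs_within(fold$train_ids, pos)
    te <- .pairs_within(fold$test_ids, pos)
    if (length(grid) == 1L) {
      sel <- rep(1L, TT)
    } else {
      err <- .inner_cv_errors(Y[tr, , drop = FALSE],
                              X[tr, , drop = FALSE],
                              pair_ids[tr, , drop = FALSE],
                              grid, inner_folds, seed + f, stimuli)
      sel <- apply(err, 2, function(e) max(which(e == min(e))))
    }
    lambda_sel[f, ] <- grid[sel]

    std <- .standardize(X[tr, , drop = FALSE])
    if (ncol(std$X) < ncol(X))
      warning("fold ", f, ": dropped zero-variance predictor(s): ",
              paste(colnames(X)[!std$keep], collapse = ", "))
    Xte <- .apply_standardization(X[te, , drop = FALSE], std)
    b <- colMeans(Y[tr, , drop = FALSE])
    Yc <- sweep(Y[tr, , drop = FALSE], 2, b)
    XtX <- crossprod(std$X)
    XtY <- crossprod(std$X, Yc)
    for (gi in unique(sel)) {
      cols <- which(sel == gi)
      W <- .nnls_gram(XtX + diag(grid[gi], ncol(std$X)),
                      XtY[, cols, drop = FALSE])
      pred_sum[te, cols] <- pred_sum[te, cols] +
        sweep(Xte %*% W, 2, b[cols], `+`)
    }
    coverage[te] <- coverage[te] + 1L
  }
  if (any(coverage == 0))
    stop(sum(coverage == 0), " pair(s) never covered by a test set")
  list(v_hat = pred_sum / coverage, coverage = coverage,
       lambda = lambda_sel)
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so generators are reproducible without disturbing
#' the session.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
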