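#' Representational dissimilarity matrices
#'
#' An `rdm` is a symmetric, zero-diagonal matrix of pairwise
#' dissimilarities between conditions (images). Its canonical vector
#' form (`rdm_vector`) lists the upper-triangle entries in row-major
#' order, i.e. pairs (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n);
#' every module in the package shares this ordering.
#'
#' @param d n x n numeric matrix, symmetric with zero diagonal.
#' @param condition_ids character vector of n condition identifiers.
#' @return An `rdm` object.
#' @export
rdm <- function(d, condition_ids = rownames(d)) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(condition_ids)) condition_ids <- sprintf("c%03d", seq_len(n))
  condition_ids <- as.character(condition_ids)
  if (length(condition_ids) != n)
    stop("condition_ids must match the matrix dimension")
  if (ncol(d) != n) stop("d must be square")
  if (!all(is.finite(d))) stop("dissimilarities must be finite")
  if (max(abs(d - t(d))) > 1e-12 * max(1, max(abs(d))))
    stop("d must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("d must have a zero diagonal")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(condition_ids, condition_ids)
  structure(list(condition_ids = condition_ids, d = d), class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d conditions, dissimilarity range [%.4g, %.4g]\n",
              length(x$condition_ids), min(x$d), max(x$d)))
  invisible(x)
}

#' Canonical pair index for n conditions
#'
#' Row-major upper-triangle enumeration: all pairs (i, j) with i < j,
#' ordered first by i then by j.
#'
#' @param n number of conditions.
#' @return two-column integer matrix with columns `i`, `j` and
#'   `n*(n-1)/2` rows.
#' @export
pair_index <- function(n) {
  if (n < 2) stop("need at least two conditions")
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  cbind(i = i, j = j)
}

#' Convert between an RDM and its canonical vector form
#'
#' `vectorize()` extracts the upper triangle in row-major order;
#' `devectorize()` rebuilds the symmetric matrix. The round trip is
#' lossless.
#'
#' @param x an [rdm()] (for `vectorize`) or `rdm_vector`
#'   (for `devectorize`).
#' @return `vectorize`: an `rdm_vector` (list with `v`, `n`,
#'   `condition_ids`); `devectorize`: an [rdm()].
#' @examples
#' r <- rdm_from_dimension(c(a = 1, b = 1, c = 0))
#' v <- vectorize(r)
#' identical(devectorize(v)$d, r$d)
#' @export
vectorize <- function(x) {
  stopifnot(inherits(x, "rdm"))
  # row-major upper triangle == column-major lower triangle of t(d)
  v <- t(x$d)[lower.tri(x$d)]
  structure(list(v = v, n = length(x$condition_ids),
                 condition_ids = x$condition_ids),
            class = "rdm_vector")
}

#' @rdname vectorize
#' @export
devectorize <- function(x) {
  stopifnot(inherits(x, "rdm_vector"))
  n <- x$n
  if (length(x$v) != n * (n - 1L) / 2L)
    stop("vector length does not match the pair count for n = ", n)
  dt <- matrix(0, n, n)
  dt[lower.tri(dt)] <- x$v
  d <- t(dt)
  rdm(d + t(d), x$condition_ids)
}

#' Single-dimension RDM by squared difference
#'
#' For one model dimension (one column of a feature matrix), the
#' dissimilarity between two images is the squared difference of their
#' values on that dimension. For a binary dimension this is 0 when the
#' feature is present or absent in both images and 1 when it is present
#' in exactly one.
#'
#' @param column named numeric vector of per-image values (names are
#'   the image ids).
#' @return An [rdm()].
#' @examples
#' rdm_from_dimension(c(im1 = 1, im2 = 1, im3 = 0))$d
#' @export
rdm_from_dimension <- function(column) {
  if (length(column) < 2) stop("need at least two images")
  if (!all(is.finite(column))) {
    bad <- names(column)[!is.finite(column)]
    if (is.null(bad)) bad <- which(!is.finite(column))
    stop("non-finite value for image(s): ", paste(bad, collapse = ", "))
  }
  d <- outer(column, column, function(a, b) (a - b)^2)
  rdm(d, names(column) %||% sprintf("c%03d", seq_along(column)))
}

#' Correlation-distance RDM from an activation matrix
#'
#' Dissimilarity between two images is 1 minus the correlation between
#' their activation vectors across units: Spearman for network-layer
#' activations, Pearson for measured response patterns. Range is
#' \[0, 2\].
#'
#' @param activations n_images x n_units numeric matrix, one row per
#'   image (rownames are image ids).
#' @param method `"spearman"` or `"pearson"`.
#' @return An [rdm()].
#' @export
rdm_correlation_distance <- function(activations,
                                     method = c("spearman", "pearson")) {
  method <- match.arg(method)
  activations <- as.matrix(activations)
  if (ncol(activations) < 2) stop("need at least two units per image")
  sds <- apply(activations, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(activations)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance activation vector for image(s): ",
         paste(bad, collapse = ", "), " (correlation undefined)")
  }
  cc <- stats::cor(t(activations), method = method)
  d <- 1 - cc
  diag(d) <- 0
  rdm(d, rownames(activations))
}

#' Weighted sum of RDMs
#'
#' Entrywise nonnegative combination of RDMs over the same conditions.
#' Weighting a model dimension by `w` before the squared-difference RDM
#' multiplies that dimension's dissimilarities by `w^2`, so a weighted
#' model RDM equals the weighted sum of single-dimension RDMs with
#' squared weights — the identity that lets fitting happen in RDM space.
#'
#' @param rdms list of [rdm()] objects over identical conditions.
#' @param weights numeric vector of nonnegative weights, one per RDM.
#' @return An [rdm()].
#' @export
weighted_sum_rdms <- function(rdms, weights) {
  if (length(rdms) != length(weights)) stop("one weight per RDM required")
  if (any(weights < 0)) stop("weights must be nonnegative")
  ids <- rdms[[1]]$condition_ids
  for (r in rdms) {
    if (!identical(r$condition_ids, ids))
      stop("all RDMs must share condition_ids")
  }
  d <- Reduce(`+`, Map(function(r, w) w * r$d, rdms, weights))
  rdm(d, ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
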