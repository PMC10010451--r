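#' Visuo-semantic model construction from labeling experiments
#'
#' Human observers first *generate* candidate feature/category labels
#' for each image; a second group then *validates* each surviving label
#' against each image. The pipeline is: keep labels generated by enough
#' observers for at least one image, binarise by validation agreement,
#' then iteratively merge highly correlated dimensions for stability
#' during fitting.
#'
#' @name label_models
NULL

#' Generation-experiment counts
#'
#' @param counts n_images x n_labels integer matrix: how many
#'   generation-experiment observers produced each label for each image
#'   (rownames: image ids; colnames: labels).
#' @param n_observers number of observers in the generation experiment
#'   (default 15).
#' @return A `generation_counts` object.
#' @export
generation_counts <- function(counts, n_observers = 15L) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts > n_observers) ||
      any(counts != round(counts)))
    stop("counts must be integers in [0, n_observers]")
  structure(list(counts = counts, n_observers = as.integer(n_observers)),
            class = "generation_counts")
}

#' Validation-experiment judgments
#'
#' @param agree n_images x n_labels integer matrix: how many
#'   validation-experiment observers ticked the label for the image.
#' @param n_observers number of observers in the validation experiment
#'   (default 14).
#' @return A `validation_judgments` object.
#' @export
validation_judgments <- function(agree, n_observers = 14L) {
  agree <- as.matrix(agree)
  if (any(agree < 0) || any(agree > n_observers) ||
      any(agree != round(agree)))
    stop("agree must be integers in [0, n_observers]")
  structure(list(agree = agree, n_observers = as.integer(n_observers)),
            class = "validation_judgments")
}

#' Select labels by generation threshold
#'
#' A label survives if at least `min_observers` observers generated it
#' for at least one image. An explicit exclusion list models the manual
#' pruning of labels inconsistent with instructions or redundant.
#'
#' @param gen a [generation_counts()].
#' @param min_observers minimum generating observers (default 3).
#' @param exclude character vector of label names to drop regardless.
#' @return Character vector of surviving label names.
#' @export
select_generated_labels <- function(gen, min_observers = 3L,
                                    exclude = character()) {
  stopifnot(inherits(gen, "generation_counts"))
  if (min_observers < 1) stop("min_observers must be at least 1")
  if (min_observers > gen$n_observers)
    stop("min_observers exceeds the number of observers")
  keep <- apply(gen$counts, 2, max) >= min_observers
  setdiff(colnames(gen$counts)[keep], exclude)
}

#' Binarise labels by validation agreement
#'
#' A cell is 1 when at least a fraction `agreement` of validation
#' observers ticked the label for that image; labels that end up
#' all-zero are dropped.
#'
#' @param val a [validation_judgments()].
#' @param agreement required agreement fraction in (0, 1\] (default
#'   0.75).
#' @param labels optional subset of labels to consider (e.g. the output
#'   of [select_generated_labels()]).
#' @param dim_group named character vector mapping label -> group tag;
#'   defaults to `"object_part"` for unknown labels.
#' @return A binary [feature_matrix()].
#' @export
validate_labels <- function(val, agreement = 0.75, labels = NULL,
                            dim_group = NULL) {
  stopifnot(inherits(val, "validation_judgments"))
  if (agreement <= 0 || agreement > 1)
    stop("agreement must lie in (0, 1]")
  agree <- val$agree
  if (!is.null(labels)) agree <- agree[, colnames(agree) %in% labels,
                                       drop = FALSE]
  values <- (agree / val$n_observers >= agreement) + 0
  keep <- colSums(values) > 0
  values <- values[, keep, drop = FALSE]
  if (ncol(values) == 0) stop("no label survived validation")
  groups <- if (is.null(dim_group)) rep("object_part", ncol(values))
            else {
              g <- dim_group[colnames(values)]
              g[is.na(g)] <- "object_part"
              g
            }
  feature_matrix(values, groups)
}

#' Iteratively merge highly correlated dimensions
#'
#' Repeatedly computes all pairwise Pearson correlations between
#' dimensions (within the same group tag) and replaces the
#' most-correlated pair by its elementwise mean, until no within-group
#' pair exceeds `r_threshold`. On binary columns Pearson equals the phi
#' coefficient; merged columns become fractional. When two pairs tie at
#' the maximal correlation, the lexicographically first pair (by
#' dimension name) is merged, making the procedure deterministic.
#'
#' @param fm a [feature_matrix()].
#' @param r_threshold merge while any within-group correlation exceeds
#'   this value (default 0.9).
#' @return A [feature_matrix()]; merged dimension names are the two
#'   input names joined with `"+"`.
#' @export
merge_correlated_dimensions <- function(fm, r_threshold = 0.9) {
  stopifnot(inherits(fm, "feature_matrix"))
  values <- fm$values
  groups <- fm$dim_group
  repeat {
    p <- ncol(values)
    if (p < 2) break
    sds <- apply(values, 2, stats::sd)
    if (any(sds == 0))
      stop("constant dimension(s) during merging: ",
           paste(colnames(values)[sds == 0], collapse = ", "))
    cc <- stats::cor(values)
    cc[lower.tri(cc, diag = TRUE)] <- -Inf
    same <- outer(groups, groups, `==`)
    cc[!same] <- -Inf
    if (max(cc) <= r_threshold) break
    # candidates at the max; lexicographic tie-break on the name pair
    hits <- which(cc == max(cc), arr.ind = TRUE)
    keypair <- function(k) {
      nm <- sort(c(colnames(values)[hits[k, 1]], colnames(values)[hits[k, 2]]))
      paste(nm, collapse = "\r")
    }
    pick <- hits[order(vapply(seq_len(nrow(hits)), keypair, "")), ,
                 drop = FALSE][1, ]
    a <- pick[1]; b <- pick[2]
    merged <- (values[, a] + values[, b]) / 2
    nm <- paste(sort(c(colnames(values)[a], colnames(values)[b])),
                collapse = "+")
    grp <- groups[a]
    keep <- setdiff(seq_len(p), c(a, b))
    values <- cbind(values[, keep, drop = FALSE], merged)
    colnames(values)[ncol(values)] <- nm
    groups <- c(groups[keep], stats::setNames(grp, nm))
  }
  feature_matrix(values, groups)
}
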