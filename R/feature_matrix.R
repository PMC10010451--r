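#' Feature matrices: images x model dimensions
#'
#' A feature matrix holds per-image values on named model dimensions in
#' \[0, 1\] — binary after label validation, possibly fractional after
#' merging correlated dimensions. Each dimension carries a group tag
#' (`color`, `texture`, `shape`, `object_part`, `subordinate`, `basic`,
#' `superordinate`, or `dnn_layer`) used for submodel grouping.
#'
#' @param values n_images x n_dims numeric matrix in \[0, 1\];
#'   rownames are image ids, colnames are dimension names.
#' @param dim_group character vector of group tags, one per dimension.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, dim_group) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("dim%03d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("img%03d", seq_len(nrow(values)))
  if (length(dim_group) != ncol(values))
    stop("one dim_group tag per dimension required")
  if (any(values < 0 | values > 1)) stop("values must lie in [0, 1]")
  if (anyDuplicated(colnames(values)))
    stop("dimension names must be unique")
  zero <- apply(values, 2, function(x) all(x == 0))
  if (any(zero))
    stop("constant-zero dimension(s): ",
         paste(colnames(values)[zero], collapse = ", "))
  structure(list(values = values,
                 dim_names = colnames(values),
                 dim_group = stats::setNames(as.character(dim_group),
                                             colnames(values))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  tab <- table(x$dim_group)
  cat(sprintf("<feature_matrix> %d images x %d dimensions (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Read and write feature matrices
#'
#' Feature matrices travel as a CSV (first column `image_id`, one
#' column per dimension) plus a JSON sidecar mapping dimension name to
#' group tag.
#'
#' @param fm a [feature_matrix()].
#' @param path CSV path; the sidecar is `<path>.groups.json`.
#' @return `read_feature_matrix` returns a [feature_matrix()];
#'   `write_feature_matrix` returns `path` invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(image_id = rownames(fm$values), fm$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(as.list(fm$dim_group),
                       paste0(path, ".groups.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  groups <- unlist(jsonlite::read_json(paste0(path, ".groups.json")))
  feature_matrix(values, groups[colnames(values)])
}
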