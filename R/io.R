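#' Read and write RDM movies as plain-text containers
#'
#' An RDM movie is stored as a long-format CSV (`time_ms`, `i`, `j`,
#' `value` over the canonical pair order) plus a JSON header carrying
#' the condition ids, time axis, participant and ROI labels. Plain
#' text keeps the containers portable and diffable; the frames
#' round-trip at full double precision.
#'
#' @param movie an [rdm_movie()].
#' @param path CSV path; the header is `<path>.header.json`.
#' @return `read_rdm_movie` returns an [rdm_movie()];
#'   `write_rdm_movie` returns `path` invisibly.
#' @export
write_rdm_movie <- function(movie, path) {
  stopifnot(inherits(movie, "rdm_movie"))
  n <- length(movie$condition_ids)
  pr <- pair_index(n)
  TT <- length(movie$times_ms)
  df <- data.frame(time_ms = rep(movie$times_ms, each = nrow(pr)),
                   i = rep(pr[, 1], TT), j = rep(pr[, 2], TT),
                   value = sprintf("%.17g", as.vector(movie$frames)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(condition_ids = movie$condition_ids,
         times_ms = movie$times_ms,
         participant_id = movie$participant_id, roi_id = movie$roi_id),
    paste0(path, ".header.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rdm_movie
#' @export
read_rdm_movie <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".header.json"),
                             simplifyVector = TRUE)
  df <- utils::read.csv(path)
  n <- length(hdr$condition_ids)
  npair <- n * (n - 1) / 2
  TT <- length(hdr$times_ms)
  if (nrow(df) != npair * TT) stop("movie CSV has unexpected row count")
  frames <- matrix(as.numeric(df$value), npair, TT)
  rdm_movie(hdr$times_ms, frames, hdr$condition_ids,
            hdr$participant_id, hdr$roi_id)
}
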