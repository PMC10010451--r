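#' Time-indexed RDM movies
#'
#' An RDM movie stacks one RDM per time point for a single participant
#' and region of interest. Internally the frames are kept in vectorised
#' form as a pairs x time matrix, which is the layout the fitting
#' stages consume.
#'
#' @param times_ms strictly increasing numeric vector of frame times in
#'   milliseconds (stimulus onset at 0); the step must be uniform.
#' @param frames pairs x time numeric matrix, column t holding the
#'   vectorised RDM at `times_ms[t]` (canonical pair order, see
#'   [pair_index()]).
#' @param condition_ids character vector of condition identifiers.
#' @param participant_id,roi_id identifying strings.
#' @return An `rdm_movie` object.
#' @export
rdm_movie <- function(times_ms, frames, condition_ids,
                      participant_id = "p01", roi_id = "roi") {
  times_ms <- as.numeric(times_ms)
  frames <- as.matrix(frames)
  n <- length(condition_ids)
  if (any(diff(times_ms) <= 0)) stop("times_ms must be strictly increasing")
  if (length(times_ms) > 2) {
    steps <- diff(times_ms)
    if (max(abs(steps - steps[1])) > 1e-9 * steps[1])
      stop("times_ms must have a uniform step")
  }
  if (nrow(frames) != n * (n - 1) / 2)
    stop("frames must have one row per condition pair")
  if (ncol(frames) != length(times_ms))
    stop("frames must have one column per time point")
  structure(list(times_ms = times_ms, frames = frames,
                 condition_ids = as.character(condition_ids),
                 participant_id = as.character(participant_id),
                 roi_id = as.character(roi_id)),
            class = "rdm_movie")
}

#' @export
print.rdm_movie <- function(x, ...) {
  cat(sprintf(
    "<rdm_movie> %s / %s: %d conditions, %d frames (%g to %g ms, step %g ms)\n",
    x$participant_id, x$roi_id, length(x$condition_ids),
    length(x$times_ms), min(x$times_ms), max(x$times_ms),
    if (length(x$times_ms) > 1) diff(x$times_ms)[1] else NA))
  invisible(x)
}

#' Extract one frame of a movie as an RDM
#'
#' @param movie an [rdm_movie()].
#' @param t frame index.
#' @return An [rdm()].
#' @export
movie_frame <- function(movie, t) {
  stopifnot(inherits(movie, "rdm_movie"))
  devectorize(structure(list(v = movie$frames[, t],
                             n = length(movie$condition_ids),
                             condition_ids = movie$condition_ids),
                        class = "rdm_vector"))
}
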