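#' Stimulus sets with category structure
#'
#' A stimulus set records, per image, one of six object categories and
#' the derived animacy / face / body-part flags used for stratified
#' cross-validation. The six categories follow the standard
#' object-vision breakdown: human body parts, human faces, animal
#' bodies, animal faces, natural objects, manmade objects.
#'
#' @param image_id character vector of unique image identifiers.
#' @param category character vector, one of
#'   `c("human_body", "human_face", "animal_body", "animal_face",
#'      "natural", "manmade")` per image.
#' @return A `stimulus_set`: data.frame with columns `image_id`,
#'   `category`, `animate`, `face`, `bodypart`.
#' @examples
#' stimulus_set(c("im1", "im2"), c("human_face", "manmade"))
#' @export
stimulus_set <- function(image_id, category) {
  image_id <- as.character(image_id)
  category <- as.character(category)
  if (length(image_id) != length(category))
    stop("image_id and category must have the same length")
  if (anyDuplicated(image_id))
    stop("image ids must be unique: ",
         paste(unique(image_id[duplicated(image_id)]), collapse = ", "))
  ok <- category %in% stimulus_categories()
  if (!all(ok))
    stop("unknown category for image(s): ",
         paste(image_id[!ok], collapse = ", "))
  out <- data.frame(
    image_id = image_id,
    category = category,
    animate  = category %in% c("human_body", "human_face",
                               "animal_body", "animal_face"),
    face     = category %in% c("human_face", "animal_face"),
    bodypart = category %in% c("human_body", "animal_body"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("stimulus_set", "data.frame")
  out
}

#' @rdname stimulus_set
#' @export
stimulus_categories <- function() {
  c("human_body", "human_face", "animal_body", "animal_face",
    "natural", "manmade")
}

#' Synthesise a stimulus set with the standard category proportions
#'
#' Category counts default to the 92-image composition used throughout
#' (12 human body parts, 12 human faces, 12 animal bodies, 12 animal
#' faces, 23 natural, 21 manmade); any other count vector can be given,
#' e.g. a scaled-down set for simulation studies.
#'
#' @param counts named integer vector of per-category image counts; the
#'   names must be the six standard categories.
#' @return A [stimulus_set()].
#' @examples
#' synth_stimuli()                  # the 92-image composition
#' synth_stimuli(scaled_counts(24)) # a 24-image scaled version
#' @export
synth_stimuli <- function(counts = c(human_body = 12, human_face = 12,
                                     animal_body = 12, animal_face = 12,
                                     natural = 23, manmade = 21)) {
  if (is.null(names(counts)) || !setequal(names(counts), stimulus_categories()))
    stop("counts must be named with the six standard categories")
  counts <- counts[stimulus_categories()]
  category <- rep(names(counts), times = counts)
  ids <- sprintf("img%03d", seq_along(category))
  stimulus_set(ids, category)
}

#' @rdname synth_stimuli
#' @param n_images total number of images to spread over categories in
#'   (approximately) the standard proportions; each of the four animate
#'   categories receives at least 2 images so stratified folds remain
#'   feasible.
#' @export
scaled_counts <- function(n_images) {
  ref <- c(human_body = 12, human_face = 12, animal_body = 12,
           animal_face = 12, natural = 23, manmade = 21)
  if (n_images < 12)
    stop("n_images too small for a feasible stratified set (need >= 12)")
  raw <- ref / sum(ref) * n_images
  counts <- pmax(floor(raw), 2L)
  # reconcile to the exact total: add by largest fractional part,
  # remove from the currently largest categories (never below 2)
  frac <- order(raw - floor(raw), decreasing = TRUE)
  k <- 0L
  while (sum(counts) < n_images) {
    counts[frac[k %% 6 + 1]] <- counts[frac[k %% 6 + 1]] + 1L
    k <- k + 1L
  }
  while (sum(counts) > n_images) {
    big <- which.max(counts)
    counts[big] <- counts[big] - 1L
  }
  counts
}
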