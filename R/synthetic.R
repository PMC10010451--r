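#' Layer specifications for synthetic network activations
#'
#' Mirrors the layer bookkeeping of the two architecture families used
#' as model predictors: a feedforward network with one processing
#' stage per visual area plus a decoder (4 areas -> 5 layers), and a
#' locally recurrent variant unrolled over time steps (4 areas x 5
#' time steps + decoder -> 21 layers); together 26 layer predictors.
#'
#' @param architecture `"feedforward"` or `"locally_recurrent"`.
#' @param n_areas number of area stages (default 4).
#' @param n_timesteps unrolled time steps (recurrent only; default 5).
#' @param include_decoder include the readout layer (default TRUE).
#' @return A `layer_spec` object.
#' @export
layer_spec <- function(architecture = c("feedforward",
                                        "locally_recurrent"),
                       n_areas = 4L, n_timesteps = 5L,
                       include_decoder = TRUE) {
  architecture <- match.arg(architecture)
  if (n_areas < 1) stop("n_areas must be at least 1")
  if (architecture == "locally_recurrent" && n_timesteps < 1)
    stop("n_timesteps must be at least 1 for the recurrent architecture")
  structure(list(architecture = architecture, n_areas = as.integer(n_areas),
                 n_timesteps = as.integer(n_timesteps),
                 include_decoder = isTRUE(include_decoder)),
            class = "layer_spec")
}

#' Enumerate the layers of a specification
#'
#' @param spec a [layer_spec()].
#' @return Ordered character vector of layer names (shallow to deep).
#' @examples
#' length(enumerate_layers(layer_spec("feedforward")))        # 5
#' length(enumerate_layers(layer_spec("locally_recurrent")))  # 21
#' @export
enumerate_layers <- function(spec) {
  stopifnot(inherits(spec, "layer_spec"))
  areas <- sprintf("area%d", seq_len(spec$n_areas))
  nm <- if (spec$architecture == "feedforward") {
    areas
  } else {
    as.vector(t(outer(areas, sprintf("t%d", seq_len(spec$n_timesteps) - 1L),
                      paste, sep = "_")))
  }
  prefix <- if (spec$architecture == "feedforward") "ff" else "rec"
  nm <- paste(prefix, nm, sep = "_")
  if (spec$include_decoder) nm <- c(nm, paste(prefix, "decoder", sep = "_"))
  nm
}

#' Synthetic layer activations with deepening category structure
#'
#' Generates one activation matrix per layer. Each image has a fixed
#' random unit-response profile; deeper layers mix in progressively
#' more of a category-prototype pattern, so layer RDMs change
#' monotonically with depth and the deepest layer's RDM correlates most
#' with the category partition. Bit-reproducible given the seed.
#'
#' @param spec a [layer_spec()].
#' @param stimuli a [stimulus_set()].
#' @param n_units units per layer (>= 2).
#' @param seed integer seed.
#' @param unit_noise_sd per-layer private unit noise (default 0.1).
#' @return Named list of n_images x n_units matrices, shallow to deep.
#' @export
generate_activations <- function(spec, stimuli, n_units = 40L, seed = 1L,
                                 unit_noise_sd = 0.1) {
  stopifnot(inherits(spec, "layer_spec"), inherits(stimuli, "stimulus_set"))
  if (n_units < 2) stop("n_units must be at least 2")
  layers <- enumerate_layers(spec)
  n <- nrow(stimuli)
  cats <- factor(stimuli$category, levels = stimulus_categories())
  local_seed(seed, {
    image_profile <- matrix(rnorm(n * n_units), n, n_units)
    prototypes <- matrix(rnorm(nlevels(cats) * n_units), nlevels(cats),
                         n_units)
    alpha <- seq(0.1, 0.9, length.out = length(layers))
    out <- lapply(seq_along(layers), function(l) {
      a <- alpha[l]
      m <- (1 - a) * image_profile +
        a * prototypes[as.integer(cats), , drop = FALSE] +
        unit_noise_sd * matrix(rnorm(n * n_units), n, n_units)
      rownames(m) <- stimuli$image_id
      m
    })
    stats::setNames(out, layers)
  })
}

#' Synthetic label-generation and validation experiments
#'
#' Plants a binary image x label ground truth derived from the
#' stimulus categories (a superordinate animacy label, basic-level
#' category labels, a handful of random object-part and color
#' features, plus a deliberate duplicate label that downstream merging
#' should collapse), then simulates per-cell observer counts for a
#' generation experiment (15 observers) and a validation experiment
#' (14 observers). With `observer_noise = 0` the validation stage
#' recovers the planted matrix exactly.
#'
#' @param stimuli a [stimulus_set()].
#' @param n_gen_observers,n_val_observers experiment sizes (15, 14).
#' @param observer_noise in \[0, 1\]: 0 = perfectly reliable observers.
#' @param seed integer seed.
#' @return List with `gen` ([generation_counts()]), `val`
#'   ([validation_judgments()]), `truth` (planted binary matrix),
#'   `dim_group` (named tags).
#' @export
generate_label_experiment <- function(stimuli, n_gen_observers = 15L,
                                      n_val_observers = 14L,
                                      observer_noise = 0.15, seed = 1L) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  n <- nrow(stimuli)
  local_seed(seed, {
    truth <- cbind(
      animate = as.numeric(stimuli$animate),
      face = as.numeric(stimuli$face),
      bodypart = as.numeric(stimuli$bodypart)
    )
    for (cat in c("natural", "manmade"))
      truth <- cbind(truth,
                     stats::setNames(data.frame(as.numeric(
                       stimuli$category == cat)), cat))
    truth <- as.matrix(truth)
    # random nameable part/color features, plus a planted duplicate
    parts <- sapply(1:3, function(k) rbinom(n, 1, 0.35))
    colnames(parts) <- sprintf("part%d", 1:3)
    colors <- sapply(1:2, function(k) rbinom(n, 1, 0.4))
    colnames(colors) <- sprintf("color%d", 1:2)
    truth <- cbind(truth, parts, colors, part1_dup = parts[, "part1"])
    # avoid degenerate all-zero / all-one columns
    for (k in seq_len(ncol(truth))) {
      if (all(truth[, k] == 0)) truth[sample(n, 2), k] <- 1
      if (all(truth[, k] == 1)) truth[sample(n, 2), k] <- 0
    }
    truth[, "part1_dup"] <- truth[, "part1"]
    rownames(truth) <- stimuli$image_id
    dim_group <- stats::setNames(
      c("superordinate", "basic", "basic", "basic", "basic",
        rep("object_part", 3), rep("color", 2), "object_part"),
      colnames(truth))

    p_gen <- ifelse(truth == 1, 1 - 0.6 * observer_noise,
                    0.08 * observer_noise)
    counts <- matrix(rbinom(length(p_gen), n_gen_observers, p_gen),
                     nrow = n, dimnames = dimnames(truth))
    p_val <- ifelse(truth == 1, 1 - 0.35 * observer_noise,
                    0.05 * observer_noise)
    agree <- matrix(rbinom(length(p_val), n_val_observers, p_val),
                    nrow = n, dimnames = dimnames(truth))
    list(gen = generation_counts(counts, n_gen_observers),
         val = validation_judgments(agree, n_val_observers),
         truth = truth, dim_group = dim_group)
  })
}

#' Piecewise-linear weight bump
#'
#' Nonnegative time course: zero before `onset_ms`, linear rise over
#' `rise_ms`, plateau at `amplitude` until `offset_ms`, linear fall
#' over `fall_ms`.
#'
#' @param times_ms time axis.
#' @param onset_ms,offset_ms plateau boundaries (ms).
#' @param rise_ms,fall_ms ramp durations (ms).
#' @param amplitude plateau height (>= 0).
#' @return Numeric vector over `times_ms`.
#' @export
weight_bump <- function(times_ms, onset_ms, offset_ms = Inf,
                        rise_ms = 20, fall_ms = 20, amplitude = 1) {
  if (amplitude < 0) stop("amplitude must be nonnegative")
  up <- pmin(pmax((times_ms - onset_ms) / rise_ms, 0), 1)
  down <- if (is.finite(offset_ms))
    pmin(pmax(1 - (times_ms - offset_ms) / fall_ms, 0), 1) else 1
  amplitude * up * down
}

#' Planted ground truth for a synthetic RDM movie
#'
#' @param weights n_predictors x n_times nonnegative matrix of planted
#'   mixing weights (rownames must name predictors).
#' @param noise_sd pattern-noise standard deviation on pair
#'   dissimilarities.
#' @param intercept homogeneous dissimilarity offset added to every
#'   pair.
#' @param n_participants number of simulated participants.
#' @param seed integer seed; fully determines the output.
#' @return A `synth_truth` object.
#' @export
synth_truth <- function(weights, noise_sd = 0.3, intercept = 1,
                        n_participants = 10L, seed = 1L) {
  weights <- as.matrix(weights)
  if (any(weights < 0)) stop("planted weights must be nonnegative")
  if (is.null(rownames(weights))) stop("weights need predictor rownames")
  structure(list(weights = weights, noise_sd = noise_sd,
                 intercept = intercept,
                 n_participants = as.integer(n_participants),
                 seed = as.integer(seed)),
            class = "synth_truth")
}

#' Generate synthetic RDM movies from a planted mixture
#'
#' Each frame's dissimilarity vector is the planted nonnegative
#' mixture of predictor RDM vectors plus a homogeneous offset, with
#' iid Gaussian noise per pair and participant. In `"pair"` mode
#' (default, matching the regression's error model) the noise is added
#' directly to the dissimilarities; in `"pattern"` mode each frame is
#' embedded into latent unit patterns, noise is added to the patterns,
#' and the frame is re-derived as a correlation-distance RDM,
#' exercising the nonlinearity of realistic measurement noise.
#'
#' @param truth a [synth_truth()].
#' @param predictors a [predictor_set()] whose names cover the rows of
#'   `truth$weights`.
#' @param times_ms time axis (one column of `truth$weights` per time).
#' @param roi_id label for the generated movies.
#' @param noise_mode `"pair"` or `"pattern"`.
#' @return List of [rdm_movie()] objects, one per participant, with
#'   the truth attached as attribute `"truth"`.
#' @export
generate_rdm_movie <- function(truth, predictors, times_ms,
                               roi_id = "roi",
                               noise_mode = c("pair", "pattern")) {
  stopifnot(inherits(truth, "synth_truth"),
            inherits(predictors, "predictor_set"))
  noise_mode <- match.arg(noise_mode)
  if (ncol(truth$weights) != length(times_ms))
    stop("weights must have one column per time point")
  miss <- setdiff(rownames(truth$weights), predictors$names)
  if (length(miss))
    stop("weights name unknown predictor(s): ",
         paste(miss, collapse = ", "))
  X <- predictors$X[, rownames(truth$weights), drop = FALSE]
  signal <- X %*% truth$weights + truth$intercept
  n <- length(predictors$condition_ids)
  movies <- local_seed(truth$seed, {
    lapply(seq_len(truth$n_participants), function(s) {
      frames <- if (noise_mode == "pair") {
        signal + truth$noise_sd * matrix(rnorm(length(signal)),
                                         nrow(signal))
      } else {
        .pattern_noise_frames(signal, n, truth$noise_sd)
      }
      rdm_movie(times_ms, frames, predictors$condition_ids,
                participant_id = sprintf("p%02d", s), roi_id = roi_id)
    })
  })
  attr(movies, "truth") <- truth
  movies
}

# embed each frame's dissimilarities as latent patterns (classical
# MDS on the double-centred Gram matrix), perturb the patterns, and
# recompute a correlation-distance frame
.pattern_noise_frames <- function(signal, n, noise_sd) {
  TT <- ncol(signal)
  out <- matrix(0, nrow(signal), TT)
  J <- diag(n) - 1 / n
  for (t in seq_len(TT)) {
    D <- devectorize(structure(list(v = signal[, t], n = n,
                                    condition_ids = sprintf("c%d", 1:n)),
                               class = "rdm_vector"))$d
    G <- -0.5 * J %*% D %*% J
    eg <- eigen(G, symmetric = TRUE)
    q <- max(2, sum(eg$values > 1e-10))
    pat <- eg$vectors[, seq_len(q), drop = FALSE] %*%
      diag(sqrt(pmax(eg$values[seq_len(q)], 0)), q)
    pat <- pat + noise_sd * matrix(rnorm(n * q), n, q)
    rownames(pat) <- sprintf("c%d", 1:n)
    out[, t] <- vectorize(rdm_correlation_distance(pat, "pearson"))$v
  }
  out
}

#' Planted early-network / late-semantic reversal scenario
#'
#' Builds two pseudo-ROI sets of synthetic RDM movies: ROI 1 loads on
#' network-layer (dnn-class) predictors with an early onset, ROI 2 on
#' visuo-semantic predictors with a later onset. All planted weights
#' are zero before stimulus onset, so the prestimulus window is pure
#' noise around the homogeneous offset. The full pipeline should
#' recover the onset ordering and find no unique semantic variance in
#' ROI 1.
#'
#' @param predictors a [predictor_set()] containing both model
#'   classes.
#' @param times_ms time axis (must include a prestimulus window).
#' @param seed integer seed.
#' @param noise_sd pair-level noise standard deviation.
#' @param n_participants participants per pseudo-ROI.
#' @param dnn_onset_ms,semantic_onset_ms planted onsets (defaults 60
#'   and 140 ms).
#' @param offset_ms end of the planted plateau (default 500 ms or the
#'   end of the epoch, whichever is earlier).
#' @param amplitude plateau weight given to each loaded predictor.
#' @param n_loaded number of predictors per class that carry signal.
#' @return List with `roi1`, `roi2` (movie lists) and `truth`
#'   (per-ROI [synth_truth()] plus the planted onsets).
#' @export
make_reversal_scenario <- function(predictors, times_ms, seed = 1L,
                                   noise_sd = 0.3, n_participants = 10L,
                                   dnn_onset_ms = 60,
                                   semantic_onset_ms = 140,
                                   offset_ms = NULL, amplitude = 1,
                                   n_loaded = 3L) {
  stopifnot(inherits(predictors, "predictor_set"))
  classes <- unique(predictors$model_class)
  if (!all(c("dnn", "visuo_semantic") %in% classes))
    stop("predictors must contain both model classes")
  if (min(times_ms) >= 0)
    stop("times_ms must include a prestimulus window")
  if (is.null(offset_ms)) offset_ms <- min(500, max(times_ms))
  bump <- function(onset) weight_bump(times_ms, onset, offset_ms,
                                      amplitude = amplitude)
  load_names <- function(class) {
    nm <- predictors$names[predictors$model_class == class]
    utils::head(nm, n_loaded)
  }
  mk_weights <- function(class, onset) {
    nm <- load_names(class)
    w <- matrix(rep(bump(onset), each = length(nm)), length(nm),
                dimnames = list(nm, NULL))
    w
  }
  truth1 <- synth_truth(mk_weights("dnn", dnn_onset_ms), noise_sd,
                        intercept = 1, n_participants = n_participants,
                        seed = seed)
  truth2 <- synth_truth(mk_weights("visuo_semantic", semantic_onset_ms),
                        noise_sd, intercept = 1,
                        n_participants = n_participants,
                        seed = seed + 1000L)
  list(roi1 = generate_rdm_movie(truth1, predictors, times_ms, "roi1"),
       roi2 = generate_rdm_movie(truth2, predictors, times_ms, "roi2"),
       truth = list(roi1 = truth1, roi2 = truth2,
                    dnn_onset_ms = dnn_onset_ms,
                    semantic_onset_ms = semantic_onset_ms))
}
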