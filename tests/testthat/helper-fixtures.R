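# Shared small fixtures, built in code.

tiny_stimuli <- function(n_images = 24L) synth_stimuli(scaled_counts(n_images))

# a feature matrix of k binary dimensions over n images, no constant columns
tiny_feature_matrix <- function(n = 10L, k = 4L, seed = 1L,
                                group = "object_part") {
  local_seed(seed, {
    repeat {
      values <- matrix(rbinom(n * k, 1, 0.5), n, k,
                       dimnames = list(sprintf("im%02d", 1:n),
                                       sprintf("dim%02d", 1:k)))
      if (all(apply(values, 2, sd) > 0)) break
    }
    feature_matrix(values, rep(group, k))
  })
}

# small predictor set: a few binary-dimension RDMs over n images
tiny_predictors <- function(stimuli, k = 6L, seed = 1L) {
  fm <- local_seed(seed, {
    repeat {
      values <- matrix(rbinom(nrow(stimuli) * k, 1, 0.5), nrow(stimuli), k,
                       dimnames = list(stimuli$image_id,
                                       sprintf("sem%02d", 1:k)))
      cc <- suppressWarnings(cor(values))
      if (all(apply(values, 2, sd) > 0) &&
          max(cc[upper.tri(cc)]) < 0.9) break
    }
    feature_matrix(values, rep("object_part", k))
  })
  group_submodels(fm)
}

# random valid RDM over n conditions
random_rdm <- function(n = 6L, seed = 1L) {
  local_seed(seed, {
    m <- matrix(runif(n * n), n)
    d <- m + t(m); diag(d) <- 0
    rdm(d, sprintf("c%02d", 1:n))
  })
}
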