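test_that("layer enumeration matches the two architecture families", {
  ff <- enumerate_layers(layer_spec("feedforward"))
  rec <- enumerate_layers(layer_spec("locally_recurrent"))
  expect_length(ff, 5)    # 4 areas + decoder
  expect_length(rec, 21)  # 4 areas x 5 time steps + decoder
  expect_length(c(ff, rec), 26)
  expect_equal(anyDuplicated(c(ff, rec)), 0L)
  expect_length(enumerate_layers(layer_spec("feedforward", n_areas = 2,
                                            include_decoder = FALSE)), 2)
  expect_error(layer_spec("locally_recurrent", n_timesteps = 0),
               "n_timesteps")
})

test_that("synthetic activations deepen category structure with depth", {
  stim <- tiny_stimuli(24)
  spec <- layer_spec("feedforward")
  a1 <- generate_activations(spec, stim, n_units = 30, seed = 5)
  a2 <- generate_activations(spec, stim, n_units = 30, seed = 5)
  expect_identical(a1, a2)
  expect_false(identical(a1,
                         generate_activations(spec, stim, 30, seed = 6)))
  expect_error(generate_activations(spec, stim, n_units = 1), "n_units")

  # category-partition RDM: 0 within category, 1 between
  cat_rdm <- vectorize(rdm(1 - outer(stim$category, stim$category, `==`) + 0,
                           stim$image_id))$v
  layer_cor <- vapply(a1, function(m)
    cor(vectorize(rdm_correlation_distance(m, "spearman"))$v, cat_rdm), 0)
  expect_gt(layer_cor[length(layer_cor)], layer_cor[1])
})

test_that("label experiment recovers the planted matrix when noiseless", {
  stim <- tiny_stimuli(24)
  lab0 <- generate_label_experiment(stim, observer_noise = 0, seed = 8)
  kept <- select_generated_labels(lab0$gen)
  expect_setequal(kept, colnames(lab0$truth))
  fm <- validate_labels(lab0$val, labels = kept,
                        dim_group = lab0$dim_group)
  expect_equal(fm$values[, colnames(lab0$truth)], lab0$truth)

  # determinism
  lab_a <- generate_label_experiment(stim, seed = 9)
  lab_b <- generate_label_experiment(stim, seed = 9)
  expect_identical(lab_a, lab_b)

  # the planted duplicate label is collapsed by merging
  merged <- merge_correlated_dimensions(fm)
  expect_lt(ncol(merged$values), ncol(fm$values))
  expect_true(any(grepl("part1\\+part1_dup|part1_dup\\+part1",
                        merged$dim_names)))
})

test_that("planted-mixture RDM movies obey their generative model", {
  stim <- tiny_stimuli(12)
  preds <- tiny_predictors(stim, k = 3, seed = 2)
  times <- c(0, 2, 4)

  # noiseless, single predictor, unit weight: every frame IS that RDM
  w1 <- matrix(1, 1, 3, dimnames = list(preds$names[1], NULL))
  mv <- generate_rdm_movie(synth_truth(w1, noise_sd = 0, intercept = 0,
                                       n_participants = 2, seed = 4),
                           preds, times)
  expect_length(mv, 2)
  for (t in 1:3)
    expect_equal(mv[[1]]$frames[, t], unname(preds$X[, 1]))

  # noiseless two-predictor mixture is exact
  w2 <- matrix(c(2, 3), 2, 3, dimnames = list(preds$names[1:2], NULL))
  mv2 <- generate_rdm_movie(synth_truth(w2, noise_sd = 0, intercept = 1,
                                        n_participants = 1, seed = 4),
                            preds, times)
  expect_equal(mv2[[1]]$frames[, 2],
               unname(2 * preds$X[, 1] + 3 * preds$X[, 2] + 1))

  expect_error(synth_truth(-w1), "nonnegative")

  # pair-level noise calibration: across many participants the
  # empirical per-pair variance matches noise_sd^2 within 10%
  w1c <- w1[, 1, drop = FALSE]
  mv3 <- generate_rdm_movie(synth_truth(w1c, noise_sd = 0.4,
                                        n_participants = 200, seed = 12),
                            preds, times_ms = 0)
  vals <- sapply(mv3, function(m) m$frames[, 1])
  expect_equal(mean(apply(vals, 1, var)), 0.4^2, tolerance = 0.1)

  # determinism across calls
  mv4 <- generate_rdm_movie(synth_truth(w1c, noise_sd = 0.4,
                                        n_participants = 200, seed = 12),
                            preds, times_ms = 0)
  expect_identical(vals, sapply(mv4, function(m) m$frames[, 1]))
})

test_that("pattern-level noise mode yields valid correlation-distance frames", {
  stim <- tiny_stimuli(12)
  preds <- tiny_predictors(stim, k = 3, seed = 2)
  w <- matrix(0.5, 1, 2, dimnames = list(preds$names[1], NULL))
  mv <- generate_rdm_movie(synth_truth(w, noise_sd = 0.2, intercept = 1,
                                       n_participants = 2, seed = 6),
                           preds, c(0, 2), noise_mode = "pattern")
  expect_true(all(mv[[1]]$frames >= 0 & mv[[1]]$frames <= 2))
  mv2 <- generate_rdm_movie(synth_truth(w, noise_sd = 0.2, intercept = 1,
                                        n_participants = 2, seed = 6),
                            preds, c(0, 2), noise_mode = "pattern")
  expect_identical(mv[[1]]$frames, mv2[[1]]$frames)
})

test_that("reversal scenario plants the intended structure", {
  stim <- tiny_stimuli(24)
  models <- build_model_predictors(run_config(n_images = 24, seed = 3))
  times <- seq(-100, 198, by = 2)
  scen <- make_reversal_scenario(models$predictors, times, seed = 7,
                                 n_participants = 3)
  # baseline: all planted weights zero before stimulus onset
  pre <- times < 0
  expect_equal(max(scen$truth$roi1$weights[, pre]), 0)
  expect_equal(max(scen$truth$roi2$weights[, pre]), 0)
  # planted semantic onset strictly later than planted dnn onset
  first_on <- function(w) min(times[colSums(w) > 0])
  expect_lt(first_on(scen$truth$roi1$weights),
            first_on(scen$truth$roi2$weights))
  # class loading is as announced
  cls <- models$predictors$model_class
  expect_true(all(cls[rownames(scen$truth$roi1$weights)] == "dnn"))
  expect_true(all(cls[rownames(scen$truth$roi2$weights)] ==
                    "visuo_semantic"))
  # baseline frames are noise around the homogeneous offset
  base_vals <- scen$roi1[[1]]$frames[, pre]
  expect_equal(mean(base_vals), scen$truth$roi1$intercept,
               tolerance = 0.05)
  expect_error(make_reversal_scenario(models$predictors,
                                      times_ms = seq(0, 100, 2)),
               "prestimulus")
})
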