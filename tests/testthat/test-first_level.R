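test_that("stratified folds have the required composition", {
  stim92 <- synth_stimuli()  # 12/12/12/12/23/21
  f <- make_fold(stim92, seed = 3)
  expect_length(f$train_ids, 84)
  expect_length(f$test_ids, 8)
  cat_of <- setNames(stim92$category, stim92$image_id)
  test_cat <- cat_of[f$test_ids]
  expect_equal(sum(test_cat %in% c("human_face", "animal_face")), 2)
  expect_equal(sum(test_cat %in% c("human_body", "animal_body")), 2)
  expect_equal(sum(test_cat %in% c("natural", "manmade")), 4)
  expect_identical(f, make_fold(stim92, seed = 3))
  expect_false(identical(f$test_ids, make_fold(stim92, seed = 4)$test_ids))

  small <- synth_stimuli(c(human_body = 2, human_face = 1,
                           animal_body = 2, animal_face = 0,
                           natural = 3, manmade = 3))
  expect_error(make_fold(small), "infeasible")
})

test_that("fold schedules reach full pair coverage (or fail loudly)", {
  toy <- synth_stimuli(c(human_body = 1, human_face = 1,
                         animal_body = 1, animal_face = 1,
                         natural = 4, manmade = 4))  # 2 faces, 2 bodyparts, 8 inanimate
  sch <- fold_schedule(toy, seed = 2, test_size = 8)
  pos <- rdmdyn:::.pair_positions(toy$image_id)
  covered <- logical(nrow(toy) * (nrow(toy) - 1) / 2)
  for (f in sch) covered[rdmdyn:::.pairs_within(f$test_ids, pos)] <- TRUE
  expect_true(all(covered))

  # a one-face composition can never cover face-face pairs
  expect_error(fold_schedule(toy, seed = 2, max_folds = 50, test_size = 4,
                             composition = c(faces = 1, bodyparts = 1,
                                             inanimate = 2)),
               "uncovered")

  # one fold of 8 test images covers only 28 of the 4186 pairs
  expect_error(fold_schedule(synth_stimuli(), seed = 1, max_folds = 1),
               "4158 of 4186")
})

test_that("nonnegative ridge fits match their contracts", {
  local_seed(11, {
    X <- scale(matrix(rnorm(40 * 3), 40, 3))
    colnames(X) <- c("p1", "p2", "p3")
    y <- drop(X %*% c(1.5, 0, 0)) + 2
  })
  f <- fit_nn_ridge(y, X, lambda = 1e-8)
  expect_gte(min(f$weights), 0)
  expect_equal(unname(f$weights["p1"]), 1.5, tolerance = 1e-4)
  expect_equal(f$intercept, 2, tolerance = 1e-8)

  # anti-correlated predictor pinned at zero by the constraint
  f2 <- fit_nn_ridge(y, cbind(anti = -scale(y)[, 1], X), lambda = 0.1)
  expect_equal(unname(f2$weights["anti"]), 0)

  # constant data: intercept-only fit
  f3 <- fit_nn_ridge(rep(3, 40), X, lambda = 1)
  expect_equal(unname(f3$weights), rep(0, 3))
  expect_equal(f3$intercept, 3)
  expect_error(fit_nn_ridge(y, X, lambda = -1), "nonnegative")

  # objective never exceeds the intercept-only objective
  for (s in 1:10) {
    local_seed(200 + s, {
      Xr <- scale(matrix(rnorm(15 * 3), 15, 3))
      yr <- rnorm(15)
      lam <- runif(1, 0, 2)
      fr <- fit_nn_ridge(yr, Xr, lam)
      expect_lte(nnridge_objective(yr, Xr, fr$weights, fr$intercept, lam),
                 nnridge_objective(yr, Xr, rep(0, 3), mean(yr), lam) + 1e-10)
    })
  }
})

test_that("solver agrees with brute-force search and lsqnonneg", {
  skip_if_not_installed("pracma")
  for (s in 1:10) {
    local_seed(300 + s, {
      npair <- sample(8:15, 1)
      p <- sample(2:3, 1)
      X <- scale(matrix(rnorm(npair * p), npair, p))
      w_true <- runif(p, 0, 2)
      y <- drop(X %*% w_true) + rnorm(npair, 0, 0.3)
      lam <- sample(c(0, 0.5), 1)
      f <- fit_nn_ridge(y, X, lam)
      w_grid <- grid_nnls_oracle(y, X, lam)
      expect_lt(max(abs(f$weights - w_grid)), 0.01)
      # independent solver cross-check at lambda = 0
      if (lam == 0) {
        yc <- y - mean(y)
        w_ls <- pracma::lsqnonneg(unclass(X), yc)$x
        expect_equal(unname(f$weights), w_ls, tolerance = 1e-6)
      }
    })
  }
})

test_that("penalty selection by nested image-level cross-validation", {
  stim <- tiny_stimuli(16)
  preds <- tiny_predictors(stim, k = 3, seed = 4)
  pr <- pair_index(16)
  pair_ids <- cbind(stim$image_id[pr[, 1]], stim$image_id[pr[, 2]])

  # single-element grid: returned as-is
  y <- preds$X %*% c(1, 2, 0) + 0.5
  expect_equal(as.numeric(select_lambda(y, preds$X, pair_ids,
                                        grid = 0.37, seed = 1)), 0.37)

  # noiseless realizable data: the smallest grid value wins
  lam <- as.numeric(select_lambda(y, preds$X, pair_ids,
                                  grid = c(1e-4, 1e-1, 10), seed = 2,
                                  stimuli = stim))
  expect_equal(lam, 1e-4)

  # constant data: every penalty ties exactly; the largest is returned
  lam_tie <- as.numeric(select_lambda(rep(1, nrow(pr)), preds$X, pair_ids,
                                      grid = c(0.1, 1, 10), seed = 3))
  expect_equal(lam_tie, 10)

  expect_error(select_lambda(y, preds$X, pair_ids, grid = c(-1, 1)),
               "nonnegative")
})

test_that("cross-validated prediction covers all pairs and recovers noiseless data", {
  stim <- tiny_stimuli(16)
  preds <- tiny_predictors(stim, k = 4, seed = 9)
  sch <- fold_schedule(stim, seed = 21, test_size = 6,
                       composition = c(faces = 2, bodyparts = 2,
                                       inanimate = 2))
  y <- drop(preds$X %*% c(1, 0.5, 2, 0)) + 1
  vec <- structure(list(v = y, n = 16, condition_ids = stim$image_id),
                   class = "rdm_vector")
  cv <- crossval_predict(vec, preds, sch, grid = c(1e-4, 1e-2),
                         inner_folds = 3, seed = 5, stimuli = stim)
  expect_true(all(cv$coverage >= 1))
  r2 <- 1 - sum((cv$v_hat - y)^2) / sum((y - mean(y))^2)
  expect_gt(r2, 0.99)

  # coverage bookkeeping: per pair, exactly the folds whose *test* set
  # contains both images contribute
  pos <- rdmdyn:::.pair_positions(stim$image_id)
  manual <- integer(length(y))
  for (f in sch) {
    idx <- rdmdyn:::.pairs_within(f$test_ids, pos)
    manual[idx] <- manual[idx] + 1L
  }
  expect_equal(cv$coverage, manual)
})

test_that("predictions are equivariant under image reordering", {
  stim <- tiny_stimuli(12)
  preds <- tiny_predictors(stim, k = 3, seed = 13)
  sch <- fold_schedule(stim, seed = 31, test_size = 6,
                       composition = c(faces = 2, bodyparts = 2,
                                       inanimate = 2))
  y <- drop(preds$X %*% c(2, 1, 0.5)) + 0.3
  vec <- structure(list(v = y, n = 12, condition_ids = stim$image_id),
                   class = "rdm_vector")
  # single-penalty grid: no inner RNG, so the fit is a deterministic
  # function of (fold ids, data) and must commute with reordering
  cv <- suppressWarnings(
    crossval_predict(vec, preds, sch, grid = 1e-3, seed = 1))

  perm <- rev(seq_len(12))
  d_perm <- devectorize(vec)$d[perm, perm]
  vec_p <- vectorize(rdm(d_perm))
  Xp <- sapply(seq_len(3), function(k) {
    vectorize(rdm(devectorize(structure(
      list(v = preds$X[, k], n = 12, condition_ids = stim$image_id),
      class = "rdm_vector"))$d[perm, perm]))$v
  })
  colnames(Xp) <- preds$names
  preds_p <- predictor_set(Xp, stim$image_id[perm], "visuo_semantic",
                           "object_part")
  cv_p <- suppressWarnings(
    crossval_predict(vec_p, preds_p, sch, grid = 1e-3, seed = 1))
  # map the permuted prediction back to the original pair order
  back <- vectorize(rdm(devectorize(structure(
    list(v = cv_p$v_hat, n = 12, condition_ids = stim$image_id[perm]),
    class = "rdm_vector"))$d[order(perm), order(perm)]))$v
  expect_equal(back, cv$v_hat, tolerance = 1e-10)
})
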