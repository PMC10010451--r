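test_that("baseline subtraction centres the prestimulus window", {
  times <- seq(-40, 58, by = 2)
  vals <- rbind(p1 = rep(2, 50), p2 = seq(0, 4.9, 0.1))
  tc <- time_course(times, vals, "total_r2", "m")
  bs <- baseline_subtract(tc, c(-40, 0))
  # constant trajectory becomes all zeros
  expect_equal(unname(bs$values[1, ]), rep(0, 50))
  # per participant, the baseline-window mean is exactly zero
  expect_equal(unname(rowMeans(bs$values[, times < 0])), c(0, 0))
  # a trajectory is shifted down by its own baseline mean
  expect_equal(bs$values[2, ], vals[2, ] - mean(vals[2, times < 0]),
               ignore_attr = TRUE)
  expect_error(baseline_subtract(tc, c(-300, -200)), "no time points")
})

test_that("signed-rank test matches exact enumeration", {
  # all 15 positive, one-sided: only the maximal rank sum reaches V
  local_seed(51, x <- rexp(15))
  expect_equal(signed_rank_test(x, "greater"), 1 / 2^15)

  # antisymmetric data: ranking is perfectly balanced, two-sided p = 1
  expect_equal(signed_rank_test(c(1, -1, 2.5, -2.5, 4, -4),
                                "two_sided"), 1)

  # zeros are discarded before ranking
  local_seed(52, x2 <- rnorm(9))
  expect_equal(signed_rank_test(c(x2, 0, 0), "greater"),
               signed_rank_test(x2, "greater"))
  expect_error(signed_rank_test(rep(0, 6)), "zero")

  # tie-free cases agree with the reference implementation
  for (s in 1:8) {
    local_seed(700 + s, xr <- rnorm(10, 0.3))
    expect_equal(signed_rank_test(xr, "greater"),
                 suppressWarnings(wilcox.test(
                   xr, alternative = "greater")$p.value))
    expect_equal(signed_rank_test(xr, "two_sided"),
                 suppressWarnings(wilcox.test(xr)$p.value))
  }

  # sign-flip boundary: p_greater(x) + p_greater(-x) = 1 + P(V = v)
  local_seed(53, xb <- rnorm(8))
  v <- sum(rank(abs(xb))[xb > 0])
  p_at_v <- dsignrank(v, 8)
  expect_equal(signed_rank_test(xb, "greater") +
                 signed_rank_test(-xb, "greater"), 1 + p_at_v)
})

test_that("FDR control by the step-up procedure", {
  # thresholds i*q/m = .0125/.025/.0375/.05: all four rejected
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(TRUE, 4))
  expect_equal(fdr_bh(rep(1, 5)), rep(FALSE, 5))
  expect_equal(fdr_bh(0.04), TRUE)   # m = 1 reduces to the alpha test
  expect_equal(fdr_bh(0.06), FALSE)
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")

  # BH rejections are a superset of Bonferroni rejections
  for (s in 1:10) {
    local_seed(800 + s, p <- runif(30)^2)
    bonf <- p <= 0.05 / length(p)
    expect_true(all(fdr_bh(p)[bonf]))
  }
})

test_that("continuity criterion removes short runs only", {
  m9 <- c(rep(FALSE, 3), rep(TRUE, 9), rep(FALSE, 5))
  expect_equal(continuity_filter(m9, 10), rep(FALSE, 17))
  m10 <- c(rep(FALSE, 3), rep(TRUE, 10), rep(FALSE, 4))
  expect_equal(continuity_filter(m10, 10), m10)
  expect_equal(continuity_filter(rep(TRUE, 25), 10), rep(TRUE, 25))

  # idempotent and monotone
  for (s in 1:10) {
    local_seed(900 + s, m <- runif(40) < 0.5)
    f1 <- continuity_filter(m, 5)
    expect_equal(continuity_filter(f1, 5), f1)
    # monotone: removing TRUEs from the input never adds survivors
    m_less <- m & (runif(40) < 0.8)
    expect_true(all(continuity_filter(m_less, 5) <= f1))
  }
})

test_that("onset extraction and significant windows", {
  times <- seq(0, 58, by = 2)
  mask <- rep(FALSE, 30); mask[11:22] <- TRUE
  expect_equal(extract_onset_from(mask, times), times[11])
  expect_true(is.na(extract_onset_from(rep(FALSE, 30), times)))

  vals <- matrix(rep(c(rep(0.001, 10), rep(0.5, 20)), each = 12), 12, 30)
  local_seed(61, vals <- vals + abs(matrix(rnorm(360, 0, 1e-4), 12)))
  tc <- time_course(times, vals, "unique_r2", "m")
  res <- infer_timecourse(tc, baseline = NULL, min_run = 10)
  expect_s3_class(res, "inference_result")
  # the continuity mask is a subset of the FDR mask
  expect_true(all(!res$sig_continuous | res$sig_fdr))
  win <- significant_windows(res)
  expect_true(nrow(win) >= 1)
  expect_equal(res$onset_ms, win$start_ms[1])
})

test_that("display filtering is zero-phase, attenuating, and display-only", {
  fs <- 500  # 2 ms sampling
  times <- seq(0, by = 2, length.out = 400)
  dc <- time_course(times, matrix(1.5, 1, 400), "total_r2", "m")
  expect_equal(display_lowpass(dc)$values, dc$values, tolerance = 1e-6)

  # a 200 Hz sinusoid is attenuated by far more than 10x at an 80 Hz
  # order-6 Butterworth (applied forward-backward)
  sine <- sin(2 * pi * 200 * times / 1000)
  tc <- time_course(times, rbind(sine), "total_r2", "m")
  sm <- display_lowpass(tc)
  mid <- 100:300
  expect_lt(max(abs(sm$values[1, mid])), max(abs(sine[mid])) / 10)

  expect_error(display_lowpass(tc, cutoff_hz = 250), "Nyquist")

  # inference never sees the filtered data: filtering does not change
  # the inference computed from the raw time course
  local_seed(71, vals <- matrix(rnorm(8 * 400, 0.2, 0.5), 8))
  tcr <- time_course(times, vals, "unique_r2", "m")
  res_raw <- infer_timecourse(tcr, baseline = NULL)
  invisible(display_lowpass(tcr))
  expect_identical(infer_timecourse(tcr, baseline = NULL), res_raw)
})
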