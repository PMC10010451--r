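#' Baseline subtraction for variance time courses
#'
#' Subtracts, per participant, the mean value over the prestimulus
#' baseline window from the whole trajectory, so post-stimulus effects
#' are tested against the prestimulus level.
#'
#' @param tc a [time_course()].
#' @param window two-element numeric `c(start, end)` in ms; the window
#'   is closed-open `[start, end)` and defaults to `[-200, 0)`.
#' @return A [time_course()] with zero baseline-window mean per
#'   participant.
#' @export
baseline_subtract <- function(tc, window = c(-200, 0)) {
  stopifnot(inherits(tc, "time_course"))
  sel <- tc$times_ms >= window[1] & tc$times_ms < window[2]
  if (!any(sel)) stop("baseline window contains no time points")
  base <- rowMeans(tc$values[, sel, drop = FALSE])
  time_course(tc$times_ms, tc$values - base, tc$measure, tc$model,
              tc$roi_id)
}

#' Wilcoxon signed-rank test against zero
#'
#' Classic signed-rank convention: zeros are discarded before ranking,
#' absolute values are ranked with average ranks. The p value comes
#' from the exact tabulated null when there are no ties, from full
#' enumeration of the 2^n sign assignments when ties are present and
#' n <= 16, and from a tie-corrected normal approximation otherwise.
#'
#' @param values per-participant numbers (differences vs 0).
#' @param alternative `"greater"` (one-sided) or `"two_sided"`.
#' @return p value (scalar).
#' @export
signed_rank_test <- function(values, alternative = c("greater",
                                                     "two_sided")) {
  alternative <- match.arg(alternative)
  x <- values[values != 0]
  if (length(x) == 0) stop("all values are zero: test undefined")
  n <- length(x)
  r <- rank(abs(x))
  v <- sum(r[x > 0])
  ties <- anyDuplicated(abs(x)) > 0
  if (!ties) {
    p_ge <- stats::psignrank(v - 1, n, lower.tail = FALSE)
    p_le <- stats::psignrank(v, n)
  } else if (n <= 16) {
    # enumerate the null distribution of V under random sign flips
    stats_null <- .signrank_null(r)
    p_ge <- mean(stats_null >= v)
    p_le <- mean(stats_null <= v)
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    p_ge <- stats::pnorm(v - 0.5, mu, sigma, lower.tail = FALSE)
    p_le <- stats::pnorm(v + 0.5, mu, sigma)
  }
  if (alternative == "greater") p_ge else min(1, 2 * min(p_ge, p_le))
}

.signrank_null <- function(ranks) {
  n <- length(ranks)
  m <- 2^n
  # bit k of assignment index selects the sign of observation k
  out <- numeric(m)
  for (k in seq_len(n)) {
    bit <- bitwAnd(seq_len(m) - 1L, bitwShiftL(1L, k - 1L)) > 0
    out <- out + ranks[k] * bit
  }
  out
}

#' Benjamini-Hochberg FDR mask across time points
#'
#' Step-up procedure controlling the expected false discovery rate at
#' `q` over one family of tests (one measure within one ROI, across
#' time points).
#'
#' @param p_values numeric vector of p values.
#' @param q target FDR level (default 0.05).
#' @param method `"BH"` (default) or `"BY"` for the
#'   arbitrary-dependence variant.
#' @return Logical rejection mask.
#' @export
fdr_bh <- function(p_values, q = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(p_values) == 0) stop("empty p-value vector")
  if (any(p_values < 0 | p_values > 1)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = method) <= q
}

#' Continuity criterion on a significance mask
#'
#' Removes significant runs shorter than `min_run` consecutive time
#' points (10 samples at 2 ms = 20 ms by default); longer runs are kept
#' verbatim. Idempotent.
#'
#' @param mask logical vector.
#' @param min_run minimum run length to survive.
#' @return Logical vector.
#' @export
continuity_filter <- function(mask, min_run = 10L) {
  r <- rle(as.logical(mask))
  r$values[r$values & r$lengths < min_run] <- FALSE
  inverse.rle(r)
}

#' Group inference on a variance time course
#'
#' Baseline-subtracts, tests each time point across participants with
#' a Wilcoxon signed-rank test, controls the FDR across time points,
#' applies the continuity criterion, and extracts the onset (first
#' time of the first surviving run).
#'
#' @param tc a [time_course()].
#' @param baseline two-element window in ms (closed-open), or `NULL`
#'   to skip baseline subtraction (e.g. for difference time courses
#'   already centred).
#' @param alternative `"greater"` or `"two_sided"`.
#' @param q FDR level (default 0.05).
#' @param min_run continuity criterion (default 10 samples).
#' @return An `inference_result`: `times_ms`, `p_values`, `sig_fdr`,
#'   `sig_continuous`, `onset_ms` (`NA` if nothing survives), `alpha`,
#'   `min_run`, plus the measure/model/roi labels.
#' @export
infer_timecourse <- function(tc, baseline = c(-200, 0),
                             alternative = c("greater", "two_sided"),
                             q = 0.05, min_run = 10L) {
  stopifnot(inherits(tc, "time_course"))
  alternative <- match.arg(alternative)
  if (!is.null(baseline)) tc <- baseline_subtract(tc, baseline)
  p <- apply(tc$values, 2, signed_rank_test, alternative = alternative)
  sig <- fdr_bh(p, q)
  sigc <- continuity_filter(sig, min_run)
  structure(list(times_ms = tc$times_ms, p_values = p, sig_fdr = sig,
                 sig_continuous = sigc,
                 onset_ms = extract_onset_from(sigc, tc$times_ms),
                 alpha = q, min_run = min_run, measure = tc$measure,
                 model = tc$model, roi_id = tc$roi_id),
            class = "inference_result")
}

#' Onset latency from an inference result
#'
#' The onset is the earliest time point that survives both FDR control
#' and the continuity criterion; `NA` when nothing survives.
#'
#' @param result an `inference_result` from [infer_timecourse()].
#' @return Onset in ms, or `NA`.
#' @export
extract_onset <- function(result) {
  stopifnot(inherits(result, "inference_result"))
  result$onset_ms
}

#' @rdname extract_onset
#' @param mask logical significance mask.
#' @param times_ms matching time axis.
#' @export
extract_onset_from <- function(mask, times_ms) {
  if (!any(mask)) return(NA_real_)
  times_ms[which(mask)[1]]
}

#' Significant windows as (start, end) runs
#'
#' @param result an `inference_result`.
#' @return data.frame with `start_ms`, `end_ms`, one row per surviving
#'   run (zero rows if none).
#' @export
significant_windows <- function(result) {
  stopifnot(inherits(result, "inference_result"))
  r <- rle(result$sig_continuous)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start_ms = result$times_ms[starts[keep]],
             end_ms = result$times_ms[ends[keep]])
}

#' Display-only low-pass filter for time courses
#'
#' Zero-phase (forward-backward) Butterworth low-pass, for plotting
#' only; statistical inference always runs on unsmoothed data.
#'
#' @param tc a [time_course()].
#' @param cutoff_hz cutoff frequency (default 80 Hz).
#' @param order filter order (default 6).
#' @return A smoothed [time_course()].
#' @export
display_lowpass <- function(tc, cutoff_hz = 80, order = 6L) {
  stopifnot(inherits(tc, "time_course"))
  dt_ms <- diff(tc$times_ms)[1]
  fs <- 1000 / dt_ms
  if (cutoff_hz >= fs / 2)
    stop("cutoff must be below the Nyquist frequency (", fs / 2, " Hz)")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # filter deviations from the row mean so a constant (DC) trajectory
  # passes through exactly despite the filter's zero-padded edges
  sm <- t(apply(tc$values, 1, function(x) {
    m <- mean(x)
    signal::filtfilt(bf, x - m) + m
  }))
  time_course(tc$times_ms, sm, tc$measure, tc$model, tc$roi_id)
}
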