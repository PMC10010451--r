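#!/usr/bin/env Rscript
# Stage 4 — group inference on the partitioned time courses.
#
# Reads the tidy time-course table from stage 3, re-runs the group
# statistics (baseline subtraction, one-sided Wilcoxon signed-rank,
# FDR 0.05 across time points, 20 ms continuity criterion), extracts
# onsets and significant windows, and checks the recovered ordering
# against the planted ground truth. Also writes a display-filtered
# (80 Hz low-pass) version of the group means for plotting.

suppressPackageStartupMessages(library(rdmdyn))

tidy <- read.csv("results/03_run/timecourses.csv")
truth <- jsonlite::read_json("results/01_ground_truth.json",
                             simplifyVector = TRUE)
cfg <- run_config(seed = 1L)

rows <- list(); smooth_rows <- list()
for (roi in unique(tidy$roi)) {
  for (ms in unique(tidy$measure)) {
    if (ms == "full_r2") next
    for (mdl in unique(tidy$model[tidy$measure == ms])) {
      sub <- tidy[tidy$roi == roi & tidy$measure == ms &
                    tidy$model == mdl, ]
      if (nrow(sub) == 0) next
      times <- sort(unique(sub$time_ms))
      parts <- sort(unique(sub$participant))
      vals <- t(vapply(parts, function(p) {
        s2 <- sub[sub$participant == p, ]
        s2$value[order(s2$time_ms)]
      }, numeric(length(times))))
      tc <- time_course(times, vals, ms, mdl, roi)
      res <- infer_timecourse(tc, baseline = c(min(times), 0),
                              q = cfg$q, min_run = cfg$min_run)
      win <- significant_windows(res)
      rows[[paste(roi, ms, mdl)]] <- data.frame(
        roi = roi, measure = ms, model = mdl, onset_ms = res$onset_ms,
        windows = paste(sprintf("[%g,%g]", win$start_ms, win$end_ms),
                        collapse = " "))
      sm <- display_lowpass(time_course(times, rbind(colMeans(vals)),
                                        ms, mdl, roi))
      smooth_rows[[paste(roi, ms, mdl)]] <- data.frame(
        roi = roi, measure = ms, model = mdl, time_ms = times,
        group_mean_smoothed = sm$values[1, ])
    }
  }
}
onsets <- do.call(rbind, rows); rownames(onsets) <- NULL
write.csv(onsets, "results/04_onsets.csv", row.names = FALSE)
write.csv(do.call(rbind, smooth_rows), "results/04_group_means_80hz.csv",
          row.names = FALSE)

print(onsets)
dnn1 <- onsets$onset_ms[onsets$roi == "roi1" &
                          onsets$measure == "unique_r2" &
                          onsets$model == "dnn"]
sem2 <- onsets$onset_ms[onsets$roi == "roi2" &
                          onsets$measure == "unique_r2" &
                          onsets$model == "visuo_semantic"]
cat(sprintf(
  "Recovered unique-variance onsets: dnn(roi1) %g ms (planted %g), semantic(roi2) %g ms (planted %g)\n",
  dnn1, truth$dnn_onset_ms, sem2, truth$semantic_onset_ms))
cat(if (isTRUE(dnn1 < sem2))
  "Planted early-network / late-semantic reversal recovered.\n"
  else "WARNING: onset ordering not recovered.\n")
cat("Wrote results/04_onsets.csv, 04_group_means_80hz.csv\n")
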