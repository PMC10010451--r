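#!/usr/bin/env Rscript
# Stage 1 — simulate the study's inputs.
#
# Builds the stimulus set (24 images in the standard category
# proportions), synthetic network-layer activations, a synthetic
# labeling experiment, and the two-ROI reversal scenario of RDM
# movies. Heavy arrays are regenerated from seeds downstream; this
# stage records the ground truth and small summaries.

suppressPackageStartupMessages(library(rdmdyn))
dir.create("results", showWarnings = FALSE)

cfg <- run_config(seed = 1L)
stim <- synth_stimuli(scaled_counts(cfg$n_images))
write.csv(stim, "results/01_stimuli.csv", row.names = FALSE)
cat("Stimulus set:", nrow(stim), "images —",
    paste(names(table(stim$category)), table(stim$category),
          collapse = ", "), "\n")

models <- build_model_predictors(cfg)
scen <- make_reversal_scenario(models$predictors, cfg$times_ms,
                               seed = cfg$seed + 307L,
                               noise_sd = cfg$noise_sd,
                               n_participants = cfg$n_participants,
                               dnn_onset_ms = cfg$dnn_onset_ms,
                               semantic_onset_ms = cfg$semantic_onset_ms)

diag <- validate_inputs(scen$roi1, models$predictors, stim,
                        cfg$composition)
cat("Input diagnostics:", if (nrow(diag) == 0) "clean" else "", "\n")
if (nrow(diag) > 0) print(diag)

truth <- list(
  seed = cfg$seed, noise_sd = cfg$noise_sd,
  intercept = scen$truth$roi1$intercept,
  n_participants = cfg$n_participants,
  dnn_onset_ms = scen$truth$dnn_onset_ms,
  semantic_onset_ms = scen$truth$semantic_onset_ms,
  roi1_loaded = rownames(scen$truth$roi1$weights),
  roi2_loaded = rownames(scen$truth$roi2$weights))
jsonlite::write_json(truth, "results/01_ground_truth.json",
                     auto_unbox = TRUE, digits = NA)

# one example movie on disk as the text-container reference
write_rdm_movie(scen$roi1[[1]], "results/01_example_movie_roi1_p01.csv")
cat("Planted onsets: dnn(roi1) =", truth$dnn_onset_ms,
    "ms, semantic(roi2) =", truth$semantic_onset_ms, "ms\n")
cat("Wrote results/01_stimuli.csv, 01_ground_truth.json,",
    "01_example_movie_roi1_p01.csv\n")
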