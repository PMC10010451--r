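#!/usr/bin/env Rscript
# Stage 2 — construct the model predictor RDMs.
#
# Runs the visuo-semantic label pipeline (generation threshold >= 3
# observers, 75% validation agreement, r > 0.9 iterative merging,
# submodel grouping) on the synthetic labeling experiment, and builds
# one correlation-distance (1 - Spearman) RDM per synthetic network
# layer. Writes the predictor inventory.

suppressPackageStartupMessages(library(rdmdyn))
dir.create("results", showWarnings = FALSE)

cfg <- run_config(seed = 1L)
stim <- synth_stimuli(scaled_counts(cfg$n_images))

lab <- generate_label_experiment(stim, observer_noise = cfg$observer_noise,
                                 seed = cfg$seed + 23L)
kept <- select_generated_labels(lab$gen)
cat("Labels surviving the generation threshold:", length(kept), "of",
    ncol(lab$gen$counts), "\n")
fm <- validate_labels(lab$val, labels = kept, dim_group = lab$dim_group)
cat("Binary dimensions after 75% validation agreement:",
    ncol(fm$values), "\n")
fm_merged <- merge_correlated_dimensions(fm)
cat("Dimensions after r > 0.9 merging:", ncol(fm_merged$values), "\n")
write_feature_matrix(fm_merged, "results/02_visuo_semantic_model.csv")

acts <- generate_activations(layer_spec("feedforward"), stim,
                             n_units = cfg$n_units, seed = cfg$seed + 11L)
dnn <- predictors_from_activations(acts, submodel = "feedforward")
sem <- group_submodels(fm_merged)
pred <- combine_predictors(dnn, sem)

inventory <- data.frame(predictor = pred$names,
                        model_class = unname(pred$model_class),
                        submodel = unname(pred$submodel),
                        rdm_mean = colMeans(pred$X),
                        rdm_sd = apply(pred$X, 2, sd))
write.csv(inventory, "results/02_predictor_inventory.csv",
          row.names = FALSE)
print(table(inventory$model_class, inventory$submodel))
cat("Wrote results/02_visuo_semantic_model.csv,",
    "02_predictor_inventory.csv\n")
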