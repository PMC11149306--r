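#!/usr/bin/env Rscript
# Step 4 -- assemble contrast tables and figures from steps 2 and 3.
#
# Reads the behavioral and neural result tables, builds the long-format
# contrast tables handed to external mixed-model tooling (steps 2/4/6 by
# ROI; within- vs between-category by moment), flags extreme outliers by
# the 3 x IQR fence, and renders the summary figures.

library(ftcp)
suppressPackageStartupMessages(library(dplyr))

out <- "results/report"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

quant <- readr::read_csv("results/neural/quantification.csv",
                         show_col_types = FALSE)
dpr <- readr::read_csv("results/behavior/dprime.csv", show_col_types = FALSE)

tabs <- make_contrast_tables(quant, dpr)
readr::write_csv(tabs$neural_contrasts, file.path(out, "neural_contrasts.csv"))
readr::write_csv(tabs$behavior_contrasts, file.path(out, "behavior_contrasts.csv"))

cat("Neural contrast table:", nrow(tabs$neural_contrasts), "rows;",
    sum(tabs$neural_contrasts$extreme_outlier), "extreme outlier(s) flagged.\n")
cat("Behavior contrast table:", nrow(tabs$behavior_contrasts), "rows;",
    sum(tabs$behavior_contrasts$extreme_outlier), "extreme outlier(s) flagged.\n")

ggplot2::ggsave(file.path(out, "sweep_amplitudes.png"),
                plot_sweep_amplitudes(quant), width = 7, height = 3.5, dpi = 150)
ggplot2::ggsave(file.path(out, "dprime_pairs.png"),
                plot_dprime_pairs(dpr), width = 7, height = 3.5, dpi = 150)

# one example psychometric fit panel (first ASC subject of step 2's cohort)
cfg <- load_design_config()
ts <- build_training_schedule(cfg$training, cfg$dimension, seed = 20 * 307 + 39)
trials <- simulate_training_responses(group_scenarios()$ASC$behavior, ts,
                                      seed = 20 * 511 + 39)
sb <- bin_training(trials, cfg$training, cfg$dimension)$stimulus_bins
fits <- dplyr::bind_rows(lapply(1:3, function(b) {
  f <- fit_psychometric(sb[sb$block == b, ], n_boot = 0)
  f$block <- b
  f
}))
ggplot2::ggsave(file.path(out, "psychometric_fit.png"),
                plot_psychometric(sb, fits), width = 7, height = 3, dpi = 150)
cat("Figures written to", out, "\n")
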