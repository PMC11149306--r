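#!/usr/bin/env Rscript
# Step 1 -- encode the experimental design and emit the trial schedules.
#
# Builds the sweep FT-EEG, same-different discrimination and category
# training schedules from the packaged design constants and writes them to
# results/design/.  The printed table is the design arithmetic every later
# step relies on.

library(ftcp)

out <- "results/design"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- load_design_config()
dim_cr <- cfg$dimension

sweep <- build_sweep_schedule(cfg$sweep, dim_cr, seed = 1)
disc <- build_discrimination_schedule(cfg$discrimination, seed = 1)
train <- build_training_schedule(cfg$training, dim_cr, seed = 1)

write_schedule(sweep, file.path(out, "sweep_schedule.csv"))
write_schedule(disc, file.path(out, "discrimination_schedule.csv"))
write_schedule(train, file.path(out, "training_schedule.csv"))

constants <- data.frame(
  quantity = c(
    "sweep trial duration (s)", "oddball presentations per step",
    "sweep trials per assessment", "discrimination trials",
    "training trials", "training stimuli", "trials per trial bin",
    "stimulus bins", "spectral resolution (Hz)", "noise bins per target",
    "z criterion (one-tailed p < .05)", "oddball harmonics summed",
    "base harmonics summed"
  ),
  value = c(
    cfg$sweep$trial_duration, cfg$sweep$presentations_per_step,
    2 * cfg$sweep$repeats_per_direction, cfg$discrimination$total_trials,
    cfg$training$total_trials, length(dim_cr$levels_training),
    cfg$training$trial_bin_size, cfg$training$stimulus_bins,
    cfg$spectrum$resolution, cfg$spectrum$n_noise_bins,
    cfg$spectrum$z_threshold, length(cfg$spectrum$oddball_harmonics),
    length(cfg$spectrum$base_harmonics)
  )
)
write.csv(constants, file.path(out, "design_constants.csv"), row.names = FALSE)

cat("Design constants:\n")
print(constants, row.names = FALSE)
cat("\nSweep schedule: ", nrow(sweep), " rows (",
    length(unique(sweep$trial)), " trials x ", cfg$sweep$n_steps,
    " steps); step 1 pairs identical stimuli, step 7 the two endpoints.\n",
    sep = "")
cat("Discrimination schedule: ", nrow(disc),
    " trials, every pair type 20x, no immediate repeats.\n", sep = "")
cat("Training schedule: ", nrow(train), " trials; boundary-zone share by",
    " block: ", paste(round(tapply(train$boundary_zone, train$block, mean), 2),
                      collapse = " / "), ".\n", sep = "")
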