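#!/usr/bin/env Rscript
# Step 3 -- simulate and quantify the sweep FT-EEG cohort.
#
# Simulates 6-trial sweep recordings (64 channels, 512 Hz) for a small
# cohort per group and assessment moment, runs the full quantification
# chain (76 s segments, zero-phase 0.1-100 Hz band-pass, 256 Hz, common
# average reference, 10 s step windows, FFT, baseline-corrected harmonic
# sums per ROI) and writes the tidy quantification table.  The cohort is
# deliberately small (4 per group) so the step runs in about a minute; the
# test suite exercises the same chain at 50 per group.

library(ftcp)
suppressPackageStartupMessages(library(dplyr))

out <- "results/neural"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 30
n_per_group <- 4

scen <- group_scenarios()
cfg <- load_design_config()
sched <- build_sweep_schedule(cfg$sweep, cfg$dimension, seed = 1)

rows <- list()
sid <- 0
for (grp in names(scen)) {
  for (s in seq_len(n_per_group)) {
    sid <- sid + 1
    for (moment in c("pre", "post")) {
      model <- neural_gen_model(tuning = scen[[grp]]$tuning[[moment]])
      rec <- simulate_sweep_recording(model, sched, cfg$sweep,
                                      seed = seed * 1009 + 2 * sid +
                                        (moment == "post"))
      q <- quantify_recording(rec, cfg$sweep, cfg$preproc, cfg$spectrum)
      q$subject <- sprintf("%s%02d", tolower(grp), s)
      q$group <- grp
      q$moment <- moment
      rows[[length(rows) + 1]] <- q
    }
  }
}
quant <- bind_rows(rows)
write.csv(quant, file.path(out, "quantification.csv"), row.names = FALSE)

cat("Summed baseline-corrected oddball amplitude (µV, OT ROIs) by step:\n")
amp <- quant |>
  filter(roi %in% c("LOT", "ROT")) |>
  group_by(group, moment, step) |>
  summarise(amplitude = round(mean(oddball_sum), 3), .groups = "drop") |>
  tidyr::pivot_wider(names_from = step, values_from = amplitude,
                     names_prefix = "step")
print(as.data.frame(amp), row.names = FALSE)
cat("\n-> amplitude increases along the sweep (step 1 ~ 0: oddball equals",
    "base);\n   the ASC boundary step (4) rises from pre to post while NT is",
    "stable.\n")

rot_lot <- quant |>
  filter(roi %in% c("LOT", "ROT"), step == 7) |>
  group_by(roi) |>
  summarise(amplitude = mean(oddball_sum), .groups = "drop")
cat(sprintf("\nRight lateralization at step 7: ROT %.3f µV vs LOT %.3f µV\n",
            rot_lot$amplitude[rot_lot$roi == "ROT"],
            rot_lot$amplitude[rot_lot$roi == "LOT"]))
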