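# Shared fixtures built in code.  Expensive simulations are cached per test
# run so several tests can reuse one recording.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Reduced sweep design: one trial per direction instead of three.  Used by
# property tests where trial averaging is not the property under test.
reduced_sweep <- function() sweep_design(repeats_per_direction = 1)

# A noiseless recording with linear tuning (2 trials, reduced design).
fixture_clean_recording <- function() {
  cached("clean_rec", {
    model <- neural_gen_model(noise_pink = 0, noise_white = 0)
    sched <- build_sweep_schedule(reduced_sweep(), dimension_spec("CR"))
    list(
      model = model,
      recording = simulate_sweep_recording(model, sched, reduced_sweep(), seed = 11)
    )
  })
}

# A noise-only recording (no evoked responses), full 6-trial design.
fixture_noise_recording <- function() {
  cached("noise_rec", {
    model <- neural_gen_model(base_amp = 0, oddball_amp = 0,
                              tuning = default_tuning("null"))
    sched <- build_sweep_schedule(sweep_design(), dimension_spec("CR"))
    list(
      model = model,
      recording = simulate_sweep_recording(model, sched, sweep_design(), seed = 12)
    )
  })
}

# Averaged per-step analysis windows for a recording.
averaged_step_windows <- function(recording, design = sweep_design(),
                                  pre_cfg = preproc_config()) {
  segs <- preprocess(recording, pre_cfg, core_s = design$trial_duration)
  wins <- lapply(segs, crop_to_steps, design = design)
  lapply(seq_len(design$n_steps), function(s) {
    average_segments(lapply(wins, `[[`, s))
  })
}

# Brute-force reference for the noise-bin selection rule, written
# independently of the package implementation.
brute_force_noise_bins <- function(amps, target) {
  cand <- c((target - 8):(target - 2), (target + 2):(target + 8))
  vals <- amps[cand]
  imax <- which(vals == max(vals))[1]
  vals2 <- vals
  vals2[imax] <- NA
  imin <- which(vals2 == min(vals2, na.rm = TRUE))[1]
  sort(cand[-c(imax, imin)])
}
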