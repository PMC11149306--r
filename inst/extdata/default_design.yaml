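# Design constants of the sweep frequency-tagging / category-learning study.
# Every value here feeds the corresponding design constructor; omitted fields
# keep the constructor defaults (which are identical to these).
dimension:
  name: CR
sweep:
  base_freq: 6.0          # Hz, base stimulation rate
  oddball_freq: 1.2       # Hz, oddball rate (every 5th image)
  n_steps: 7
  step_duration: 10       # s per sweep step (12 oddball presentations)
  repeats_per_direction: 3
  fade_s: 1.67
discrimination:
  repeats_per_pair: 20    # x 10 pair types = 200 trials
  blocks: 4
training:
  blocks: 3
  trials_per_block: 150
  boundary_fractions: [.na, 0.60, 0.80]
  boundary_zone_size: 20
  trial_bin_size: 15
  stimulus_bins: 10
preproc:
  bandpass: [0.1, 100.0]  # Hz, fourth-order Butterworth, zero phase
  filter_order: 4
  resample_to: 256        # Hz
  segment_pad: [2, 4]     # s before / after the 70 s core -> 76 s segments
  interp_neighbors: 3
spectrum:
  window_s: 10            # s -> 0.1 Hz resolution
  neighborhood: 8         # bins each side
  exclude_adjacent: 1
  z_threshold: 1.64       # one-tailed p < .05
  base_freq: 6.0
  oddball_freq: 1.2
  max_harmonic: 6
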