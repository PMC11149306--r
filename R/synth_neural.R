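#' Generative model for sweep FT-EEG recordings
#'
#' Describes the statistical structure the quantification pipeline assumes:
#' phase-locked sinusoidal steady-state responses at the 6 Hz base rate and
#' its harmonics (medial-occipital scalp topography), an oddball response at
#' 1.2 Hz and its harmonics (occipito-temporal topography with a right > left
#' factor) whose amplitude follows a per-step tuning curve, and a 1/f^gamma +
#' white noise background.  All response frequencies are integer multiples of
#' 0.1 Hz so they land on exact analysis bins for 10 s windows.
#'
#' @param base_amp Peak base-response amplitude (microvolt) at the
#'   medial-occipital maximum.
#' @param oddball_amp Peak oddball-response amplitude (microvolt) at the left
#'   occipito-temporal maximum; the right hemisphere is scaled by
#'   `right_lateralization`.
#' @param tuning Length-7 oddball gain per sweep step, non-decreasing is
#'   typical; `tuning[1]` must be 0 (an oddball identical to the base elicits
#'   no oddball response).
#' @param harmonic_decay Geometric amplitude factor per harmonic.
#' @param n_harmonics Harmonics generated per response.
#' @param right_lateralization Right/left oddball amplitude factor.
#' @param profile_width Gaussian width (grid steps) of the scalp profiles.
#' @param noise_pink Amplitude spectral density (microvolt/sqrt(Hz)) of the
#'   1/f^gamma component at 1 Hz.
#' @param noise_white White-noise floor (microvolt/sqrt(Hz)).
#' @param noise_band Upper band limit of the synthesized noise (Hz); the
#'   default sits well above the analysed band and the preprocessing
#'   low-pass edge.
#' @param gamma Spectral slope of the pink component (power 1/f^gamma).
#' @param sfreq Sampling rate (Hz).
#' @param layout Electrode layout tibble, see [biosemi64_layout()].
#' @return A `neural_gen_model` with derived per-channel amplitude profiles
#'   `base_profile` and `oddball_profile` (named numeric vectors, microvolt).
#' @export
neural_gen_model <- function(base_amp = 2, oddball_amp = 0.6,
                             tuning = default_tuning("linear"),
                             harmonic_decay = 0.6, n_harmonics = 6,
                             right_lateralization = 1.3, profile_width = 1.6,
                             noise_pink = 0.10, noise_white = 0.02,
                             noise_band = 120, gamma = 1,
                             sfreq = 512, layout = biosemi64_layout()) {
  stopifnot(length(tuning) == 7)
  if (abs(tuning[1]) > 1e-12) {
    stop("tuning[1] must be 0: an oddball identical to the base elicits no oddball response")
  }
  if (any(tuning < 0) || base_amp < 0 || oddball_amp < 0) {
    stop("amplitudes and tuning gains must be non-negative")
  }
  if (gamma < 0) stop("gamma must be >= 0")
  gauss_at <- function(center_label, width) {
    c0 <- unlist(layout[layout$label == center_label, c("x", "y")])
    exp(-((layout$x - c0[1])^2 + (layout$y - c0[2])^2) / (2 * width^2))
  }
  base_profile <- base_amp * gauss_at("Oz", profile_width)
  oddball_profile <- oddball_amp * pmax(
    gauss_at("PO7", profile_width),
    right_lateralization * gauss_at("PO8", profile_width)
  )
  names(base_profile) <- names(oddball_profile) <- layout$label
  model <- list(
    base_amp = base_amp, oddball_amp = oddball_amp, tuning = tuning,
    harmonic_decay = harmonic_decay, n_harmonics = n_harmonics,
    right_lateralization = right_lateralization,
    base_profile = base_profile, oddball_profile = oddball_profile,
    noise_pink = noise_pink, noise_white = noise_white,
    noise_band = noise_band, gamma = gamma,
    sfreq = sfreq, layout = layout
  )
  class(model) <- "neural_gen_model"
  model
}

#' Built-in oddball tuning curves
#'
#' Per-step oddball gains used as scenario building blocks: `"linear"` rises
#' evenly along the sweep (no categorical structure); `"categorical"` adds a
#' boundary bump at step 4, the step that contrasts stimuli across the
#' trained category boundary; `"null"` is all-zero.
#'
#' @param shape One of `"linear"`, `"categorical"`, `"null"`.
#' @return Numeric length-7 gain vector with first element 0.
#' @export
default_tuning <- function(shape = c("linear", "categorical", "null")) {
  shape <- match.arg(shape)
  switch(shape,
    linear = c(0, 1, 2, 3, 4, 5, 6) / 6,
    categorical = c(0, 0.15, 0.30, 0.65, 0.75, 0.90, 1),
    null = rep(0, 7)
  )
}

#' Simulate a sweep FT-EEG recording
#'
#' Generates a continuous 64-channel recording at the model's sampling rate
#' containing every trial of the supplied sweep schedule: a 70 s stimulation
#' core per trial (flanked by 1.67 s fade ramps outside the core) with
#' sinusoidal base and oddball responses, embedded in seeded 1/f + white
#' noise, and event markers at each stimulation-core onset.  Trials are
#' spaced so that 76 s analysis segments (2 s before to 4 s after the core)
#' never overlap.
#'
#' @param model A [neural_gen_model()].
#' @param schedule A sweep schedule from [build_sweep_schedule()].
#' @param design The [sweep_design()] the schedule was built from.
#' @param seed Integer seed for the noise synthesis.
#' @param lead_s Quiet lead-in before the first trial (seconds); must cover
#'   the pre-trial analysis pad.
#' @return An `ftcp_recording`: list with `data` (samples x channels matrix,
#'   microvolt), `sfreq`, `ch_names`, `layout`, `events` (tibble of `sample`,
#'   `code`, `trial`, `direction`) and `model` parameters echoed for
#'   provenance.
#' @export
simulate_sweep_recording <- function(model, schedule, design = sweep_design(),
                                     seed = 1L, lead_s = 4) {
  trials <- unique(schedule[, c("trial", "direction")])
  trials <- trials[order(trials$trial), ]
  n_trials <- nrow(trials)
  fs <- model$sfreq
  core_s <- design$trial_duration
  period_s <- core_s + 8  # >= 2 s pre-pad + 4 s post-pad + fade ramps
  if (lead_s < 2) stop("lead_s must cover the 2 s pre-trial analysis pad")
  total_s <- lead_s + n_trials * period_s
  n_samp <- round(total_s * fs)
  n_ch <- nrow(model$layout)

  noise <- synth_noise(n_samp, n_ch, fs, model$noise_pink, model$noise_white,
                       model$gamma, band = model$noise_band, seed = seed)

  onsets <- round((lead_s + (seq_len(n_trials) - 1L) * period_s) * fs) + 1L
  base_wave <- numeric(n_samp)
  odd_wave <- numeric(n_samp)
  n_fade <- round(design$fade_s * fs)
  n_core <- round(core_s * fs)
  n_step <- round(design$step_duration * fs)
  harm <- seq_len(model$n_harmonics)
  decay <- model$harmonic_decay^(harm - 1)
  for (tr in seq_len(n_trials)) {
    i0 <- onsets[tr] - n_fade           # fade-in start
    idx <- i0:(onsets[tr] + n_core + n_fade - 1L)
    t_rel <- (idx - onsets[tr]) / fs    # 0 at core onset
    envelope <- rep(1, length(idx))
    envelope[t_rel < 0] <- 1 + t_rel[t_rel < 0] / design$fade_s
    post <- t_rel >= core_s
    envelope[post] <- 1 - (t_rel[post] - core_s) / design$fade_s
    # per-sample oddball gain: step-wise tuning, fades carry the edge steps
    step_at <- pmin(pmax(floor(t_rel / design$step_duration) + 1, 1),
                    design$n_steps)
    gain <- model$tuning[step_at]
    bw <- rowSums(vapply(
      harm,
      function(h) decay[h] * sin(2 * pi * design$base_freq * h * t_rel),
      numeric(length(idx))
    ))
    ow <- rowSums(vapply(
      harm,
      function(h) decay[h] * sin(2 * pi * design$oddball_freq * h * t_rel),
      numeric(length(idx))
    ))
    base_wave[idx] <- base_wave[idx] + envelope * bw
    odd_wave[idx] <- odd_wave[idx] + envelope * gain * ow
  }
  data <- noise +
    tcrossprod(base_wave, model$base_profile) +
    tcrossprod(odd_wave, model$oddball_profile)
  colnames(data) <- model$layout$label

  events <- tibble::tibble(
    sample = onsets, code = "sweep_onset",
    trial = trials$trial, direction = trials$direction
  )
  rec <- list(
    data = data, sfreq = fs, ch_names = model$layout$label,
    layout = model$layout, events = events,
    tuning = model$tuning, oddball_profile = model$oddball_profile,
    base_profile = model$base_profile
  )
  class(rec) <- "ftcp_recording"
  rec
}

#' @export
print.ftcp_recording <- function(x, ...) {
  cat(sprintf(
    "<ftcp_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
    ncol(x$data), nrow(x$data), x$sfreq, nrow(x$data) / x$sfreq,
    nrow(x$events)
  ))
  invisible(x)
}

# Frequency-domain noise synthesis: independent per channel, Hermitian
# spectrum with Rayleigh bin magnitudes matching the one-sided amplitude
# spectral density asd(f) = white + pink * f^(-gamma/2), in microvolt/sqrt(Hz).
synth_noise <- function(n_samp, n_ch, fs, pink, white, gamma, band = fs / 2,
                        seed = 1L) {
  if (pink == 0 && white == 0) return(matrix(0, n_samp, n_ch))
  n_fft <- stats::nextn(n_samp, c(2, 3, 5))  # 5-smooth length, truncated below
  with_rng(seed, {
    freqs <- seq_len(floor((n_fft - 1) / 2)) * fs / n_fft
    freqs <- freqs[freqs <= band]
    asd <- white + pink * freqs^(-gamma / 2)
    # E|c_k|^2 = PSD(f) * fs * n / 2  (two-sided FFT coefficient scaling)
    sc <- sqrt(asd^2 * fs * n_fft / 4)
    half <- length(freqs)
    # two real channels per complex inverse FFT: the inverse transform of
    # S_a + i S_b (both Hermitian) is a + i b
    n_pair <- ceiling(n_ch / 2)
    spec <- matrix(complex(real = 0), n_fft, n_pair)
    for (pr in seq_len(n_pair)) {
      mk_half <- function() complex(real = rnorm(half, sd = sc),
                                    imaginary = rnorm(half, sd = sc))
      ha <- mk_half()
      hb <- if (2 * pr <= n_ch) mk_half() else complex(real = numeric(half))
      spec[2:(half + 1), pr] <- ha + 1i * hb
      spec[n_fft:(n_fft - half + 1), pr] <- Conj(ha) + 1i * Conj(hb)
    }
    z <- stats::mvfft(spec, inverse = TRUE) / n_fft
    out <- matrix(0, n_samp, n_ch)
    keep <- seq_len(n_samp)
    for (pr in seq_len(n_pair)) {
      out[, 2 * pr - 1] <- Re(z[keep, pr])
      if (2 * pr <= n_ch) out[, 2 * pr] <- Im(z[keep, pr])
    }
    out
  })
}

#' Injected oddball amplitude implied by the generative model
#'
#' The ground-truth per-channel amplitude of one oddball harmonic at a given
#' sweep step, as seen by the analysis chain.  Because every channel carries
#' the same waveform scaled by its profile value, common-average
#' re-referencing maps the per-channel amplitude `a_c` to
#' `a_c - mean_c(a_c)`; recovery checks must compare against the
#' re-referenced value.
#'
#' @param model A [neural_gen_model()].
#' @param channel Channel label.
#' @param step Sweep step (gain `tuning[step]`).
#' @param harmonic Oddball harmonic number.
#' @param reference `"common_average"` (default, matching [preprocess()]) or
#'   `"none"`.
#' @return Scalar amplitude (microvolt).
#' @export
injected_oddball_amplitude <- function(model, channel, step = 7, harmonic = 1,
                                       reference = c("common_average", "none")) {
  reference <- match.arg(reference)
  prof <- model$oddball_profile * model$harmonic_decay^(harmonic - 1) *
    model$tuning[step]
  if (reference == "common_average") prof <- prof - mean(prof)
  unname(prof[channel])
}

#' Export recording events as TSV
#'
#' @param recording An `ftcp_recording`.
#' @param path Output file.
#' @export
write_events_tsv <- function(recording, path) {
  ev <- recording$events
  ev$onset_s <- (ev$sample - 1) / recording$sfreq
  readr::write_tsv(ev, path)
  invisible(path)
}
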