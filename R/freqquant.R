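#' Preprocessing configuration
#'
#' @param bandpass Band edges in Hz (zero-phase fourth-order Butterworth).
#' @param filter_order Butterworth order (applied forward and backward).
#' @param resample_to Target sampling rate in Hz.
#' @param segment_pad Seconds kept before / after each stimulation core;
#'   with a 70 s core the defaults give 76 s segments.
#' @param interp_neighbors Neighbours used for bad-channel interpolation.
#' @return A `preproc_config`.
#' @export
preproc_config <- function(bandpass = c(0.1, 100), filter_order = 4,
                           resample_to = 256, segment_pad = c(2, 4),
                           interp_neighbors = 3) {
  if (bandpass[1] <= 0 || bandpass[1] >= bandpass[2]) {
    stop("bandpass edges must satisfy 0 < low < high")
  }
  if (bandpass[2] >= resample_to / 2) {
    stop("bandpass high edge must be below the post-resampling Nyquist rate")
  }
  cfg <- list(
    bandpass = bandpass, filter_order = filter_order,
    resample_to = resample_to, segment_pad = segment_pad,
    interp_neighbors = interp_neighbors, reference = "common_average"
  )
  class(cfg) <- "preproc_config"
  cfg
}

#' Spectrum / harmonic-quantification configuration
#'
#' @param window_s Analysis window per sweep step (s); 10 s windows give the
#'   0.1 Hz spectral resolution.
#' @param neighborhood Noise-bin search half-width (bins each side).
#' @param exclude_adjacent Bins directly adjacent to the target excluded.
#' @param z_threshold One-tailed significance criterion for harmonics
#'   (1.64 = the 5% one-tailed normal critical value to two decimals).
#' @param base_freq,oddball_freq Stimulation frequencies (Hz).
#' @param max_harmonic Highest harmonic considered for the oddball response.
#' @return A `spectrum_config` carrying the derived oddball and base harmonic
#'   sets: oddball harmonics 1..6 of 1.2 Hz excluding the 6 Hz base frequency
#'   (five summed harmonics), base harmonics 6, 12, 18, 24 Hz.
#' @export
spectrum_config <- function(window_s = 10, neighborhood = 8,
                            exclude_adjacent = 1, z_threshold = 1.64,
                            base_freq = 6, oddball_freq = 1.2,
                            max_harmonic = 6) {
  odd_all <- oddball_freq * seq_len(max_harmonic)
  is_base_multiple <- abs(odd_all / base_freq - round(odd_all / base_freq)) < 1e-9
  cfg <- list(
    window_s = window_s, resolution = 1 / window_s,
    neighborhood = neighborhood, exclude_adjacent = exclude_adjacent,
    n_noise_bins = 2L * (neighborhood - exclude_adjacent) - 2L,
    z_threshold = z_threshold,
    base_freq = base_freq, oddball_freq = oddball_freq,
    max_harmonic = max_harmonic,
    oddball_harmonics = odd_all[!is_base_multiple],
    base_harmonics = base_freq * (1:4)
  )
  class(cfg) <- "spectrum_config"
  cfg
}

#' Segment, filter, resample and re-reference a recording
#'
#' Cuts one segment per stimulation-core onset event (`segment_pad[1]` s
#' before to `core + segment_pad[2]` s after), applies the zero-phase
#' fourth-order Butterworth band-pass (the two-pass squared magnitude
#' response applied in the frequency domain, with reflective edge padding to
#' suppress wrap-around transients), decimates to the target rate,
#' optionally interpolates bad channels, and re-references every sample to
#' the common average.
#'
#' @param recording An `ftcp_recording`.
#' @param cfg A [preproc_config()].
#' @param core_s Stimulation-core duration per trial (s).
#' @param bad_labels Channels to interpolate before re-referencing.
#' @return A list of `ftcp_segment` objects (one per trial): `data`
#'   (samples x channels at `resample_to` Hz), `sfreq`, `ch_names`, `layout`,
#'   `trial`, `direction`, `core_start` (sample index of the core onset).
#' @export
preprocess <- function(recording, cfg = preproc_config(), core_s = 70,
                       bad_labels = character()) {
  ev <- recording$events[recording$events$code == "sweep_onset", ]
  if (nrow(ev) == 0) stop("recording carries no sweep_onset events")
  fs <- recording$sfreq
  dec <- fs / cfg$resample_to
  if (abs(dec - round(dec)) > 1e-9) {
    stop("sampling rate must be an integer multiple of resample_to")
  }
  dec <- as.integer(round(dec))
  n_pre <- round(cfg$segment_pad[1] * fs)
  n_len <- round((cfg$segment_pad[1] + core_s + cfg$segment_pad[2]) * fs)
  n_reflect <- round(10 * fs)
  if (n_reflect %% dec != 0) n_reflect <- n_reflect + dec - n_reflect %% dec

  raw <- lapply(seq_len(nrow(ev)), function(i) {
    start <- ev$sample[i] - n_pre
    if (start < 1 || start + n_len - 1 > nrow(recording$data)) {
      stop("trial ", ev$trial[i], ": segment pads exceed the recording bounds")
    }
    recording$data[start:(start + n_len - 1L), , drop = FALSE]
  })
  filtered <- butterworth_bandpass(raw, fs, cfg$bandpass, cfg$filter_order,
                                   n_reflect, decimate = dec)
  lapply(seq_len(nrow(ev)), function(i) {
    filt <- filtered[[i]]
    colnames(filt) <- recording$ch_names
    out <- list(
      data = filt, sfreq = cfg$resample_to, ch_names = recording$ch_names,
      layout = recording$layout, trial = ev$trial[i],
      direction = ev$direction[i],
      core_start = round(cfg$segment_pad[1] * cfg$resample_to) + 1L
    )
    class(out) <- "ftcp_segment"
    if (length(bad_labels)) {
      out <- interpolate_channels(out, bad_labels, recording$layout,
                                  n_neighbors = cfg$interp_neighbors)
    }
    out$data <- out$data - rowMeans(out$data)  # common average reference
    out
  })
}

# Zero-phase Butterworth band-pass: reflective padding at both ends, then
# the forward-backward (squared) order-n Butterworth magnitude response
# |H_lp|^2 |H_hp|^2 applied to the FFT of each channel, followed by
# decimation expressed as spectrum folding.  Equivalent to forward-backward
# IIR filtering plus sample picking, without per-channel transient handling.
# Accepts one samples x channels matrix or a list of equally sized matrices
# (batched in a single FFT; two real channels ride in one complex column).
butterworth_bandpass <- function(seg, fs, bandpass, order, n_reflect,
                                 decimate = 1L) {
  segs <- if (is.list(seg)) seg else list(seg)
  n <- nrow(segs[[1]])
  n_ch <- ncol(segs[[1]])
  np <- n + 2L * n_reflect
  if (np %% decimate != 0) stop("padded length must be divisible by the decimation factor")
  reflect_pad <- function(x) {
    rbind(
      2 * x[rep(1, n_reflect), , drop = FALSE] - x[(n_reflect + 1):2, , drop = FALSE],
      x,
      2 * x[rep(n, n_reflect), , drop = FALSE] - x[(n - 1):(n - n_reflect), , drop = FALSE]
    )
  }
  cols <- do.call(cbind, lapply(segs, reflect_pad))
  m <- ncol(cols)
  n_pair <- ceiling(m / 2)
  zin <- matrix(complex(real = 0), np, n_pair)
  for (pr in seq_len(n_pair)) {
    b <- if (2 * pr <= m) cols[, 2 * pr] else 0
    zin[, pr] <- complex(real = cols[, 2 * pr - 1], imaginary = b)
  }
  f <- c(seq(0, floor(np / 2)), seq(-ceiling(np / 2) + 1, -1)) * fs / np
  fa <- abs(f)
  gain <- 1 / (1 + (fa / bandpass[2])^(2 * order))
  pos <- fa > 0
  gain[pos] <- gain[pos] / (1 + (bandpass[1] / fa[pos])^(2 * order))
  gain[!pos] <- 0
  zf <- stats::mvfft(zin) * gain
  nd <- np %/% decimate
  if (decimate > 1L) {
    # y[seq(1, np, by = D)] = ifft_{np/D} of the D-fold aliased spectrum / D
    folded <- zf[seq_len(nd), , drop = FALSE]
    for (j in seq_len(decimate - 1L)) {
      folded <- folded + zf[j * nd + seq_len(nd), , drop = FALSE]
    }
    zf <- folded / decimate
  }
  z <- stats::mvfft(zf, inverse = TRUE) / nd
  keep <- (n_reflect %/% decimate + 1L):((n_reflect + n) %/% decimate)
  out_n <- length(keep)
  res <- lapply(segs, function(s) matrix(0, out_n, n_ch))
  for (pr in seq_len(n_pair)) {
    ca <- 2 * pr - 1
    si <- (ca - 1) %/% n_ch + 1L
    res[[si]][, (ca - 1) %% n_ch + 1L] <- Re(z[keep, pr])
    if (2 * pr <= m) {
      cb <- 2 * pr
      sj <- (cb - 1) %/% n_ch + 1L
      res[[sj]][, (cb - 1) %% n_ch + 1L] <- Im(z[keep, pr])
    }
  }
  if (is.list(seg)) res else res[[1]]
}

#' Interpolate bad channels from their nearest neighbours
#'
#' Each bad channel is replaced by the unweighted mean of its `n_neighbors`
#' spatially nearest good channels (Euclidean distance on the scalp layout).
#'
#' @param segment An `ftcp_segment` (or any list with a samples x channels
#'   `data` matrix and `ch_names`).
#' @param bad_labels Channel labels to replace.
#' @param layout Layout tibble with `label`, `x`, `y`.
#' @param n_neighbors Number of good neighbours averaged.
#' @return The segment with bad channels replaced.
#' @export
interpolate_channels <- function(segment, bad_labels, layout = segment$layout,
                                 n_neighbors = 3) {
  if (length(bad_labels) == 0) return(segment)
  unknown <- setdiff(bad_labels, segment$ch_names)
  if (length(unknown)) stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  good <- setdiff(segment$ch_names, bad_labels)
  if (length(good) < n_neighbors) {
    stop("need at least ", n_neighbors, " good channels to interpolate")
  }
  in_roi <- intersect(bad_labels, unlist(default_rois()))
  if (length(in_roi)) {
    warning("interpolating channel(s) inside an analysis ROI: ",
            paste(in_roi, collapse = ", "))
  }
  d <- layout_distances(layout)
  for (bad in bad_labels) {
    nb <- good[order(d[bad, good])][seq_len(n_neighbors)]
    segment$data[, bad] <- rowMeans(segment$data[, nb, drop = FALSE])
  }
  segment
}

#' Crop a segment into per-step analysis windows
#'
#' Splits the stimulation core into the design's sweep steps, each window
#' containing an integer number of oddball cycles (12 cycles of 1.2 Hz in a
#' 10 s step: 2560 samples at 256 Hz).
#'
#' @param segment An `ftcp_segment` from [preprocess()].
#' @param design The [sweep_design()].
#' @return A list of `design$n_steps` matrices (samples x channels), with
#'   attributes `step`, `n_cycles`, `sfreq`, `trial`, `direction`.
#' @export
crop_to_steps <- function(segment, design = sweep_design()) {
  fs <- segment$sfreq
  n_cycles <- floor(design$step_duration * design$oddball_freq + 1e-9)
  if (n_cycles < 1) stop("step shorter than one oddball cycle")
  n_win <- n_cycles / design$oddball_freq * fs
  if (abs(n_win - round(n_win)) > 1e-6) {
    stop("an integer number of oddball cycles does not align with the sampling grid")
  }
  n_win <- as.integer(round(n_win))
  n_step <- round(design$step_duration * fs)
  lapply(seq_len(design$n_steps), function(s) {
    i0 <- segment$core_start + (s - 1L) * n_step
    w <- segment$data[i0:(i0 + n_win - 1L), , drop = FALSE]
    attr(w, "step") <- s
    attr(w, "n_cycles") <- n_cycles
    attr(w, "sfreq") <- fs
    attr(w, "trial") <- segment$trial
    attr(w, "direction") <- segment$direction
    w
  })
}

#' Average analysis windows in the time domain
#'
#' Pointwise mean over windows belonging to the same condition (dimension x
#' sweep step across trials); phase-locked responses are preserved while
#' noise power shrinks with the number of windows.
#'
#' @param windows A list of equally sized samples x channels matrices.
#' @return The averaged matrix with an `n_averaged` attribute (step/sfreq
#'   attributes carried over from the first window).
#' @export
average_segments <- function(windows) {
  if (length(windows) == 0) stop("no windows to average")
  dims <- vapply(windows, dim, integer(2))
  if (any(dims != dims[, 1])) stop("windows differ in size; cannot average")
  out <- Reduce(`+`, windows) / length(windows)
  for (a in c("step", "n_cycles", "sfreq")) {
    attr(out, a) <- attr(windows[[1]], a)
  }
  attr(out, "n_averaged") <- length(windows)
  out
}

#' Single-sided amplitude spectrum
#'
#' FFT amplitude per frequency bin with peak-amplitude normalisation: a pure
#' sinusoid of peak amplitude A at an exact bin frequency reads A at that
#' bin.  Bin width is `sfreq / n_samples` (0.1 Hz for 10 s windows).
#'
#' @param window Samples x channels matrix (a vector is treated as one
#'   channel).
#' @param sfreq Sampling rate in Hz (defaults to the window's `sfreq`
#'   attribute).
#' @return An `ftcp_spectrum`: list with `freq`, `amp` (bins x channels),
#'   `bin_width`, `ch_names`.
#' @export
amplitude_spectrum <- function(window, sfreq = attr(window, "sfreq")) {
  if (is.null(dim(window))) window <- matrix(window, ncol = 1)
  n <- nrow(window)
  if (n < 2) stop("window must contain at least 2 samples")
  co <- stats::mvfft(window)
  n_keep <- floor(n / 2) + 1L
  amp <- abs(co[seq_len(n_keep), , drop = FALSE]) * 2 / n
  amp[1, ] <- amp[1, ] / 2
  if (n %% 2 == 0) amp[n_keep, ] <- amp[n_keep, ] / 2
  spec <- list(
    freq = (seq_len(n_keep) - 1) * sfreq / n,
    amp = amp,
    bin_width = sfreq / n,
    ch_names = colnames(window)
  )
  class(spec) <- "ftcp_spectrum"
  spec
}

#' Map a frequency to its spectrum bin index
#'
#' @param spectrum An `ftcp_spectrum`.
#' @param hz Frequency in Hz; must land on an exact bin.
#' @return Integer bin index (1-based, DC = 1).
#' @export
freq_to_bin <- function(spectrum, hz) {
  idx <- as.integer(round(hz / spectrum$bin_width)) + 1L
  if (idx < 1L || idx > length(spectrum$freq) ||
      abs(spectrum$freq[idx] - hz) > 1e-6) {
    stop("frequency ", hz, " Hz does not fall on an analysis bin (bin width ",
         spectrum$bin_width, " Hz)")
  }
  idx
}

#' Select the 12 surrounding noise bins for a target bin
#'
#' Candidate bins are the 8 on each side of the target; the two directly
#' adjacent bins are excluded, and of the remaining 14 the single maximum-
#' and single minimum-amplitude bins are dropped (ties broken towards the
#' lowest index), leaving exactly 12.
#'
#' @param amps Numeric amplitude vector (one channel).
#' @param target_idx Target bin index.
#' @param neighborhood,exclude_adjacent See [spectrum_config()].
#' @return Integer vector of 12 bin indices.
#' @export
noise_bins <- function(amps, target_idx, neighborhood = 8, exclude_adjacent = 1) {
  lo <- target_idx - neighborhood
  hi <- target_idx + neighborhood
  if (lo < 1 || hi > length(amps)) {
    stop("target bin ", target_idx, " is too close to the spectrum edge")
  }
  offsets <- setdiff(-neighborhood:neighborhood, -exclude_adjacent:exclude_adjacent)
  cand <- target_idx + offsets
  vals <- amps[cand]
  imax <- which.max(vals)  # ties: lowest index
  rest <- setdiff(seq_along(vals), imax)
  imin <- rest[which.min(vals[rest])]
  cand[-c(imax, imin)]
}

#' Baseline-corrected amplitude at a target bin
#'
#' Amplitude at the target minus the mean amplitude over its 12 surrounding
#' noise bins; may be negative.
#'
#' @inheritParams noise_bins
#' @return Scalar amplitude (same unit as `amps`).
#' @export
baseline_corrected_amplitude <- function(amps, target_idx, neighborhood = 8,
                                         exclude_adjacent = 1) {
  nb <- noise_bins(amps, target_idx, neighborhood, exclude_adjacent)
  amps[target_idx] - mean(amps[nb])
}

#' z-score of a target bin against its surrounding noise bins
#'
#' `(amp(target) - mean(noise)) / sd(noise)` with the sample SD taken over
#' the same 12 noise bins used for baseline correction.
#'
#' @inheritParams noise_bins
#' @return Scalar z (NA with a warning if the noise SD is zero).
#' @export
zscore_bin <- function(amps, target_idx, neighborhood = 8, exclude_adjacent = 1) {
  nb <- noise_bins(amps, target_idx, neighborhood, exclude_adjacent)
  s <- sd(amps[nb])
  if (!is.finite(s) || s == 0) {
    warning("noise SD is zero at bin ", target_idx, "; z-score undefined")
    return(NA_real_)
  }
  (amps[target_idx] - mean(amps[nb])) / s
}

#' Determine consecutive significant harmonics
#'
#' Evaluates harmonics `1..max_harmonic` of the fundamental on a (grand
#' averaged, channel-pooled) amplitude spectrum: a harmonic is significant
#' when its surrounding-bin z-score exceeds the one-tailed criterion.
#' Harmonics coinciding with frequencies in `exclude_hz` (e.g. the base
#' stimulation frequency when testing the oddball response) are excluded
#' from the returned set without breaking the run; otherwise retention is
#' consecutive from the first harmonic, stopping at the first
#' non-significant one.
#'
#' @param amps Pooled amplitude vector.
#' @param bin_width Spectral bin width (Hz).
#' @param fundamental_hz Fundamental frequency (Hz).
#' @param max_harmonic Highest harmonic evaluated.
#' @param exclude_hz Frequencies excluded from the returned set.
#' @param z_threshold Significance criterion.
#' @return A tibble with `harmonic`, `freq`, `z`, `significant`, `excluded`,
#'   `retained`; the retained harmonic set is `freq[retained]`.
#' @export
significant_harmonics <- function(amps, bin_width, fundamental_hz,
                                  max_harmonic = 6, exclude_hz = numeric(),
                                  z_threshold = 1.64) {
  spec_stub <- list(bin_width = bin_width, freq = (seq_along(amps) - 1) * bin_width)
  class(spec_stub) <- "ftcp_spectrum"
  out <- tibble::tibble(
    harmonic = seq_len(max_harmonic),
    freq = fundamental_hz * seq_len(max_harmonic)
  )
  out$z <- vapply(out$freq, function(hz) {
    zscore_bin(amps, freq_to_bin(spec_stub, hz))
  }, numeric(1))
  out$significant <- !is.na(out$z) & out$z > z_threshold
  out$excluded <- vapply(out$freq, function(hz) {
    any(abs(exclude_hz - hz) < 1e-9)
  }, logical(1))
  run_alive <- TRUE
  retained <- logical(max_harmonic)
  for (i in seq_len(max_harmonic)) {
    if (out$excluded[i]) next  # excluded harmonics neither count nor break the run
    if (run_alive && out$significant[i]) retained[i] <- TRUE else run_alive <- FALSE
  }
  out$retained <- retained
  out
}

#' Summed baseline-corrected response over a harmonic set
#'
#' Sums the baseline-corrected amplitudes at the given harmonic frequencies
#' per channel, then averages over the requested channels (ROI).
#'
#' @param spectrum An `ftcp_spectrum`.
#' @param harmonics_hz Harmonic frequencies to sum (5 oddball harmonics or
#'   the 4 base-rate harmonics under the default configuration).
#' @param channels Channel labels to average over (default: all).
#' @return Scalar summed amplitude.
#' @export
summed_response <- function(spectrum, harmonics_hz, channels = spectrum$ch_names) {
  if (length(harmonics_hz) == 0) stop("harmonic set is empty")
  per_ch <- summed_response_by_channel(spectrum, harmonics_hz)
  missing <- setdiff(channels, names(per_ch))
  if (length(missing)) stop("unknown channel(s): ", paste(missing, collapse = ", "))
  mean(per_ch[channels])
}

#' @rdname summed_response
#' @return `summed_response_by_channel()`: named vector of per-channel sums.
#' @export
summed_response_by_channel <- function(spectrum, harmonics_hz) {
  idx <- vapply(harmonics_hz, function(hz) freq_to_bin(spectrum, hz), integer(1))
  sums <- apply(spectrum$amp, 2, function(a) {
    sum(vapply(idx, function(i) baseline_corrected_amplitude(a, i), numeric(1)))
  })
  names(sums) <- spectrum$ch_names
  sums
}

#' Data-driven ROI channel selection
#'
#' Retains every electrode whose summed baseline-corrected response across
#' subjects exceeds the across-channel grand mean at one-tailed Bonferroni
#' significance (one-sample z using the between-subject SD), and groups the
#' retained electrodes into contiguous scalp clusters.
#'
#' @param responses Subjects x channels matrix of summed responses (columns
#'   named by electrode label).
#' @param layout Scalp layout tibble.
#' @param alpha Family-wise alpha before Bonferroni division.
#' @param n_tests Number of tests for the Bonferroni correction.
#' @param cluster_radius Maximum grid distance joining retained electrodes
#'   into one cluster.
#' @return A tibble with `label`, `mean`, `z`, `p`, `retained`, `cluster`
#'   (NA for non-retained channels).
#' @export
select_roi_channels <- function(responses, layout = biosemi64_layout(),
                                alpha = 0.05, n_tests = ncol(responses),
                                cluster_radius = 1.5) {
  if (is.null(colnames(responses))) stop("responses must carry channel names")
  n_sub <- nrow(responses)
  if (n_sub < 2) stop("need at least 2 subjects for a dispersion estimate")
  ch_mean <- colMeans(responses)
  ch_sd <- apply(responses, 2, sd)
  if (any(ch_sd == 0)) stop("zero between-subject dispersion for some channels")
  grand <- mean(ch_mean)
  z <- (ch_mean - grand) / (ch_sd / sqrt(n_sub))
  p <- pnorm(z, lower.tail = FALSE)
  retained <- p < alpha / n_tests
  out <- tibble::tibble(
    label = colnames(responses), mean = unname(ch_mean),
    z = unname(z), p = unname(p), retained = unname(retained)
  )
  out$cluster <- NA_integer_
  if (any(retained)) {
    keep <- out$label[out$retained]
    d <- layout_distances(layout)[keep, keep, drop = FALSE]
    adj <- d <= cluster_radius
    cluster <- integer(length(keep))
    cl <- 0L
    for (i in seq_along(keep)) {
      if (cluster[i] == 0L) {
        cl <- cl + 1L
        frontier <- i
        cluster[i] <- cl
        while (length(frontier)) {
          nb <- which(adj[frontier[1], ] & cluster == 0L)
          cluster[nb] <- cl
          frontier <- c(frontier[-1], nb)
        }
      }
    }
    out$cluster[match(keep, out$label)] <- cluster
  }
  out
}

#' Quantify a sweep recording
#'
#' Full per-recording chain: preprocess into 76 s segments, crop each into
#' the 7 sweep-step windows, average windows per step across trials
#' (collapsing sweep direction), compute amplitude spectra, and return the
#' summed baseline-corrected oddball and base-rate responses per step x ROI
#' together with per-harmonic z-scores on the ROI-pooled spectrum.
#'
#' @param recording An `ftcp_recording`.
#' @param design The [sweep_design()].
#' @param pre_cfg A [preproc_config()].
#' @param spec_cfg A [spectrum_config()].
#' @param rois Named list of ROI channel sets (see [default_rois()]).
#' @param bad_labels Channels interpolated during preprocessing.
#' @return A tibble: `step`, `roi`, `oddball_sum`, `base_sum`,
#'   `z_h1`..`z_h<max>` (oddball harmonic z-scores on the ROI-pooled
#'   spectrum), `is_contrast_step` (steps 2, 4, 6: the within/boundary/within
#'   analysis contrasts), `n_trials`.
#' @export
quantify_recording <- function(recording, design = sweep_design(),
                               pre_cfg = preproc_config(),
                               spec_cfg = spectrum_config(),
                               rois = default_rois(),
                               bad_labels = character()) {
  segments <- preprocess(recording, pre_cfg, core_s = design$trial_duration,
                         bad_labels = bad_labels)
  windows <- lapply(segments, crop_to_steps, design = design)
  n_trials <- length(segments)
  per_step <- lapply(seq_len(design$n_steps), function(s) {
    average_segments(lapply(windows, `[[`, s))
  })
  rows <- lapply(seq_len(design$n_steps), function(s) {
    spec <- amplitude_spectrum(per_step[[s]], sfreq = pre_cfg$resample_to)
    dplyr::bind_rows(lapply(names(rois), function(rn) {
      ch <- rois[[rn]]
      pooled <- rowMeans(spec$amp[, ch, drop = FALSE])
      zs <- vapply(spec_cfg$oddball_freq * seq_len(spec_cfg$max_harmonic),
                   function(hz) zscore_bin(pooled, freq_to_bin(spec, hz)),
                   numeric(1))
      row <- tibble::tibble(
        step = s, roi = rn,
        oddball_sum = summed_response(spec, spec_cfg$oddball_harmonics, ch),
        base_sum = summed_response(spec, spec_cfg$base_harmonics, ch),
        n_trials = n_trials
      )
      for (h in seq_along(zs)) row[[paste0("z_h", h)]] <- zs[h]
      row
    }))
  })
  out <- dplyr::bind_rows(rows)
  out$is_contrast_step <- out$step %in% c(2, 4, 6)
  out
}

#' Quantify a cohort of sweep recordings
#'
#' Applies [quantify_recording()] to a set of recordings and binds the
#' results into one tidy table keyed by subject, group, dimension and
#' assessment moment.
#'
#' @param recordings A list of `ftcp_recording` objects.
#' @param meta A data frame with one row per recording: `subject`, `group`,
#'   `dimension`, `moment`.
#' @param ... Passed to [quantify_recording()].
#' @return A tidy tibble (one row per recording x step x ROI).
#' @export
sweep_quantification <- function(recordings, meta, ...) {
  if (length(recordings) != nrow(meta)) {
    stop("need one meta row per recording")
  }
  dplyr::bind_rows(lapply(seq_along(recordings), function(i) {
    q <- quantify_recording(recordings[[i]], ...)
    dplyr::bind_cols(meta[rep(i, nrow(q)), , drop = FALSE], q)
  }))
}
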