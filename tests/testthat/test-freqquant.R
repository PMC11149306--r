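test_that("preprocessing removes DC, preserves the passband and re-references", {
  fs <- 512
  t <- (seq_len(480 * fs) - 1) / fs
  lay <- biosemi64_layout()
  # channel 1: DC offset; channel 2: pure 6 Hz; rest small structured signal
  data <- matrix(0.01 * sin(2 * pi * 3 * t), length(t), 64)
  data[, 1] <- 5
  data[, 2] <- 2 * sin(2 * pi * 6 * t)
  colnames(data) <- lay$label
  rec <- structure(
    list(data = data, sfreq = fs, ch_names = lay$label, layout = lay,
         events = tibble::tibble(sample = 3 * fs + 1L, code = "sweep_onset",
                                 trial = 1L, direction = "forward")),
    class = "ftcp_recording"
  )
  segs <- preprocess(rec)
  seg <- segs[[1]]
  expect_equal(nrow(seg$data), 76 * 256)
  expect_equal(seg$sfreq, 256)
  # common average: per-sample channel mean is zero
  expect_lt(max(abs(rowMeans(seg$data))), 1e-9)

  # re-do without the CAR confound: single-channel checks through the filter
  dc <- butterworth_bandpass(matrix(5, 4096, 1), fs, c(0.1, 100), 4, 1024)
  expect_lt(max(abs(dc)), 0.05)
  mid <- 2000:30000
  sine <- butterworth_bandpass(matrix(2 * sin(2 * pi * 6 * t[1:38912]), ncol = 1),
                               fs, c(0.1, 100), 4, 5120)
  expect_equal(max(abs(sine[mid, 1])), 2, tolerance = 0.01)  # passband flatness
})

test_that("frequency-domain decimation equals filter-then-pick-samples", {
  set.seed(42)
  x <- matrix(rnorm(38912 * 3), ncol = 3)
  full <- butterworth_bandpass(x, 512, c(0.1, 100), 4, 5120, decimate = 1L)
  dec <- butterworth_bandpass(x, 512, c(0.1, 100), 4, 5120, decimate = 2L)
  expect_equal(dec, full[seq(1, nrow(full), by = 2), ], tolerance = 1e-10)
})

test_that("preprocess errors name the offending trial", {
  fx <- fixture_clean_recording()
  rec <- fx$recording
  rec$events$sample[1] <- 100L  # pad before onset exceeds recording start
  expect_error(preprocess(rec), "trial 1")
  rec$events <- rec$events[0, ]
  expect_error(preprocess(rec), "no sweep_onset events")
})

test_that("bad channels are rebuilt from their three nearest neighbours", {
  lay <- biosemi64_layout()
  seg <- structure(list(
    data = matrix(rnorm(200 * 64), 200, 64, dimnames = list(NULL, lay$label)),
    sfreq = 256, ch_names = lay$label, layout = lay
  ), class = "ftcp_segment")

  # brute-force nearest-3 search, independent of the package helper
  d2 <- outer(lay$x, lay$x, "-")^2 + outer(lay$y, lay$y, "-")^2
  for (bad in c("Cz", "F5", "P2")) {
    bi <- match(bad, lay$label)
    nn <- lay$label[setdiff(order(d2[bi, ]), bi)][1:3]
    out <- interpolate_channels(seg, bad, lay)
    expect_equal(out$data[, bad], rowMeans(seg$data[, nn]))
  }
  # identical neighbours reproduce the shared signal exactly
  seg2 <- seg
  nn_oz <- lay$label[setdiff(order(d2[match("Oz", lay$label), ]),
                             match("Oz", lay$label))][1:3]
  shared <- rnorm(200)
  for (ch in nn_oz) seg2$data[, ch] <- shared
  # Oz sits inside the medial-occipital ROI: interpolated, but with a warning
  expect_warning(out2 <- interpolate_channels(seg2, "Oz", lay), "ROI")
  expect_equal(out2$data[, "Oz"], shared)
  # no-op and error paths
  expect_identical(interpolate_channels(seg, character(), lay), seg)
  expect_error(interpolate_channels(seg, "Xx9", lay), "unknown channel")
})

test_that("cropping yields 7 aligned windows of exactly 12 oddball cycles", {
  fx <- fixture_clean_recording()
  segs <- preprocess(fx$recording)
  wins <- crop_to_steps(segs[[1]])
  expect_length(wins, 7)
  expect_true(all(vapply(wins, nrow, integer(1)) == 2560))  # 12 / 1.2 * 256
  expect_true(all(vapply(wins, function(w) attr(w, "n_cycles"), numeric(1)) == 12))
  expect_error(crop_to_steps(segs[[1]], sweep_design(step_duration = 0.5,
                                                     oddball_freq = 2)),
               NA)  # 1 cycle windows still legal
})

test_that("amplitude spectrum uses peak normalisation and satisfies Parseval", {
  fs <- 256
  n <- 2560
  t <- (seq_len(n) - 1) / fs
  x <- 2 * sin(2 * pi * 6 * t) + 0.5 * sin(2 * pi * 1.2 * t + 0.7)
  spec <- amplitude_spectrum(x, fs)
  expect_equal(spec$bin_width, 0.1)
  expect_equal(spec$amp[freq_to_bin(spec, 6), 1], 2, tolerance = 1e-9)
  expect_equal(spec$amp[freq_to_bin(spec, 1.2), 1], 0.5, tolerance = 1e-9)
  others <- spec$amp[-c(freq_to_bin(spec, 6), freq_to_bin(spec, 1.2)), 1]
  expect_lt(max(others), 1e-9)
  # Parseval: sum of squared single-sided amplitudes = 2 x variance
  set.seed(1)
  y <- rnorm(n)
  y <- y - mean(y)
  specy <- amplitude_spectrum(y, fs)
  expect_equal(sum(specy$amp[-1, 1]^2) / 2, mean(y^2), tolerance = 2e-3)
  expect_error(amplitude_spectrum(1, fs), "at least 2 samples")
  expect_error(freq_to_bin(spec, 6.05), "does not fall on an analysis bin")
})

test_that("noise-bin selection matches the brute-force rule", {
  set.seed(7)
  for (i in 1:50) {
    amps <- abs(rnorm(60))
    target <- sample(9:51, 1)
    nb <- noise_bins(amps, target)
    expect_length(nb, 12)
    expect_true(all(abs(nb - target) >= 2 & abs(nb - target) <= 8))
    expect_equal(sort(nb), brute_force_noise_bins(amps, target))
  }
  # flat spectrum: deterministic lowest-index tie-break, still 12 bins
  flat <- rep(1, 40)
  expect_equal(noise_bins(flat, 20), setdiff(20 + c(-(8:2), 2:8), c(12, 13)))
  expect_error(noise_bins(flat, 5), "too close to the spectrum edge")
})

test_that("baseline correction and z-scores follow their definitions", {
  # flat spectrum of constant amplitude -> 0
  expect_equal(baseline_corrected_amplitude(rep(3, 40), 20), 0)
  # isolated peak on a zero background -> the peak amplitude
  amps <- rep(0, 40)
  amps[20] <- 1.7
  expect_equal(baseline_corrected_amplitude(amps, 20), 1.7)
  # invariance to adding a constant to the whole spectrum
  set.seed(11)
  r <- abs(rnorm(40))
  expect_equal(baseline_corrected_amplitude(r + 5, 20),
               baseline_corrected_amplitude(r, 20), tolerance = 1e-12)
  # crafted spectrum: 12 noise bins with mean 2 and SD 1, sentinels dropped
  a <- sqrt(11 / 12)
  crafted <- rep(2, 45)
  nbvals <- 2 + rep(c(-a, a), 6)
  crafted[22 + c(-(8:3), 3:8)] <- nbvals
  crafted[22 + 2] <- 100    # max sentinel, dropped
  crafted[22 - 2] <- -100   # min sentinel, dropped
  crafted[22] <- 10
  expect_equal(sd(nbvals), 1)
  expect_equal(zscore_bin(crafted, 22), 8)
  expect_equal(baseline_corrected_amplitude(crafted, 22), 8)
  # target equal to the noise mean -> z = 0
  crafted[22] <- 2
  expect_equal(zscore_bin(crafted, 22), 0)
  # degenerate flat spectrum: undefined z
  expect_warning(z <- zscore_bin(rep(1, 40), 20), "undefined")
  expect_true(is.na(z))
})

test_that("the z > 1.64 rule has the calibrated (liberal) false-positive rate", {
  # Amplitude-spectrum bins of Gaussian noise are Rayleigh; with the mean and
  # SD estimated from the 12 surrounding bins (max and min of 14 dropped) the
  # true exceedance rate of z > 1.64 sits near 0.14, not at the nominal 0.05.
  # Independent oracle: direct Monte Carlo on Rayleigh draws.
  set.seed(21)
  oracle <- mean(replicate(20000, {
    amps <- sqrt(rnorm(30)^2 + rnorm(30)^2)
    (amps[15] - mean(amps[brute_force_noise_bins(amps, 15)])) /
      sd(amps[brute_force_noise_bins(amps, 15)])
  }) > 1.64)
  # pipeline rate on noise-only recordings
  fx <- fixture_noise_recording()
  wins <- averaged_step_windows(fx$recording, sweep_design())
  zs <- unlist(lapply(wins, function(w) {
    spec <- amplitude_spectrum(w, 256)
    targets <- seq(41, 1001, by = 17)  # >= 4 Hz, spaced beyond the bin pool
    apply(spec$amp, 2, function(a) {
      vapply(targets, function(ti) zscore_bin(a, ti), numeric(1))
    })
  }))
  rate <- mean(zs > 1.64)
  expect_gt(length(zs), 2000)
  se <- sqrt(oracle * (1 - oracle) * (1 / length(zs) + 1 / 20000))
  expect_lt(abs(rate - oracle), 4 * se + 0.01)
})

test_that("consecutive significant harmonics reproduce the five-harmonic rule", {
  # high-SNR synthetic pooled spectrum: oddball harmonics 1..6 all strong
  set.seed(3)
  amps <- abs(rnorm(300, 0.05, 0.01))
  bw <- 0.1
  for (h in 1:6) amps[h * 12 + 1] <- amps[h * 12 + 1] + 1
  res <- significant_harmonics(amps, bw, 1.2, max_harmonic = 6,
                               exclude_hz = 6, z_threshold = 1.64)
  expect_equal(res$freq[res$retained], c(1.2, 2.4, 3.6, 4.8, 7.2))
  expect_equal(sum(res$retained), 5)
  # a gap at harmonic 3 breaks the run even if harmonic 5 is significant
  amps2 <- abs(rnorm(300, 0.05, 0.01))
  for (h in c(1, 2, 5)) amps2[h * 12 + 1] <- amps2[h * 12 + 1] + 1
  res2 <- significant_harmonics(amps2, bw, 1.2, max_harmonic = 6,
                                exclude_hz = 6, z_threshold = 1.64)
  expect_equal(res2$freq[res2$retained], c(1.2, 2.4))
  # threshold -Inf retains all candidates minus exclusions
  res3 <- significant_harmonics(amps, bw, 1.2, max_harmonic = 6,
                                exclude_hz = 6, z_threshold = -Inf)
  expect_equal(sum(res3$retained), 5)
  expect_false(res3$retained[res3$freq == 6])
})

test_that("summed responses add the right number of addends", {
  cfg <- spectrum_config()
  expect_equal(length(cfg$oddball_harmonics), 5)
  expect_equal(cfg$oddball_harmonics, c(1.2, 2.4, 3.6, 4.8, 7.2))
  expect_equal(cfg$base_harmonics, c(6, 12, 18, 24))
  # zero-noise sinusoids with known per-harmonic amplitudes
  fs <- 256
  n <- 2560
  t <- (seq_len(n) - 1) / fs
  h_amp <- c(0.5, 0.3, 0.2, 0.1, 0.05, 0.02)
  x <- rowSums(vapply(1:6, function(h) h_amp[h] * sin(2 * pi * 1.2 * h * t),
                      numeric(n)))
  w <- matrix(c(x, 2 * x), ncol = 2, dimnames = list(NULL, c("a", "b")))
  spec <- amplitude_spectrum(w, fs)
  total <- sum(h_amp[-5])  # 6 Hz (harmonic 5) excluded
  expect_equal(summed_response(spec, cfg$oddball_harmonics, "a"), total,
               tolerance = 1e-9)
  expect_equal(summed_response(spec, cfg$oddball_harmonics, c("a", "b")),
               1.5 * total, tolerance = 1e-9)
  expect_error(summed_response(spec, numeric()), "empty")
  expect_error(summed_response(spec, 1.2, "nope"), "unknown channel")
})

test_that("ROI selection retains the generative topography", {
  lay <- biosemi64_layout()
  prof <- neural_gen_model()$oddball_profile
  set.seed(9)
  n_sub <- 30
  responses <- matrix(rnorm(n_sub * 64, mean = rep(prof, each = n_sub),
                            sd = 0.02), n_sub, 64)
  colnames(responses) <- lay$label
  sel <- select_roi_channels(responses, lay)
  expect_true(all(c("P8", "PO8", "P10") %in% sel$label[sel$retained]))
  expect_false(any(c("Fpz", "Fz", "Cz") %in% sel$label[sel$retained]))
  # retained channels group into contiguous left/right clusters
  expect_true(all(!is.na(sel$cluster[sel$retained])))
  lot <- sel$cluster[sel$label == "PO7"]
  rot <- sel$cluster[sel$label == "PO8"]
  expect_false(is.na(lot) || is.na(rot))
  expect_true(lot != rot)
  # equal channels: nothing exceeds the mean
  flat <- matrix(rnorm(n_sub * 64, 1, 0.01), n_sub, 64,
                 dimnames = list(NULL, lay$label))
  expect_equal(sum(select_roi_channels(flat, lay)$retained), 0)
  # degenerate threshold: alpha = 1 with a single test keeps all
  # above-the-mean channels
  sel1 <- select_roi_channels(responses, lay, alpha = 1, n_tests = 2)
  expect_equal(sel1$retained, sel1$z > 0)
})

test_that("quantified sweep amplitudes track the generative tuning curve", {
  # property over seeds at default (high) SNR, reduced 2-trial design
  tun <- default_tuning("linear")
  sched <- build_sweep_schedule(reduced_sweep(), dimension_spec("CR"))
  cors <- vapply(1:5, function(s) {
    model <- neural_gen_model(tuning = tun)
    rec <- simulate_sweep_recording(model, sched, reduced_sweep(), seed = 100 + s)
    q <- quantify_recording(rec, reduced_sweep())
    rot <- q[q$roi == "ROT", ]
    stats::cor(rot$oddball_sum, tun[rot$step])
  }, numeric(1))
  expect_true(all(cors > 0.95))
})

test_that("cohort quantification binds per-recording tables with metadata", {
  fx <- fixture_clean_recording()
  meta <- tibble::tibble(subject = c("s01", "s01"), group = "NT",
                         dimension = "CR", moment = c("pre", "post"))
  tab <- sweep_quantification(list(fx$recording, fx$recording), meta,
                              design = reduced_sweep())
  expect_equal(nrow(tab), 2 * 7 * 3)
  expect_setequal(unique(tab$moment), c("pre", "post"))
  expect_true(all(c("subject", "group", "dimension", "moment", "step", "roi",
                    "oddball_sum", "base_sum") %in% names(tab)))
  # identical recordings quantify identically regardless of metadata
  expect_equal(tab$oddball_sum[tab$moment == "pre"],
               tab$oddball_sum[tab$moment == "post"])
  expect_error(sweep_quantification(list(fx$recording), meta), "one meta row")
})

test_that("step 1 shows no oddball response and flags mark steps 2/4/6", {
  fx <- fixture_noise_recording()
  q0 <- quantify_recording(fx$recording)
  expect_equal(sort(unique(q0$step[q0$is_contrast_step])), c(2, 4, 6))
  expect_equal(nrow(q0), 7 * 3)
  # noise-only: all steps indistinguishable from zero
  expect_lt(max(abs(q0$oddball_sum)), 0.05)
  fx2 <- fixture_clean_recording()
  q1 <- quantify_recording(fx2$recording, reduced_sweep())
  expect_lt(abs(q1$oddball_sum[q1$step == 1 & q1$roi == "ROT"]), 0.01)
  expect_gt(q1$oddball_sum[q1$step == 7 & q1$roi == "ROT"], 0.5)
})
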