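#' Stimulus dimension specification
#'
#' Describes one of the two orthogonal shape dimensions (aspect ratio `AR` or
#' curvature `CR`) as signed percent levels around the dimension midpoint.
#' The assessment continuum has 7 levels in steps of 33% from midpoint to the
#' endpoints; the training continuum has 50 levels in steps of 4%.  The
#' category boundary sits at the midpoint (0%).
#'
#' @param name `"AR"` or `"CR"`.
#' @return An object of class `dimension_spec` with fields
#'   `name`, `levels_assessment` (length 7), `levels_training` (length 50)
#'   and `boundary` (0).
#' @export
#' @examples
#' dimension_spec("CR")$levels_assessment
dimension_spec <- function(name = c("AR", "CR")) {
  name <- match.arg(name)
  levels_assessment <- seq(-99, 99, by = 33)
  levels_training <- seq(-98, 98, by = 4)
  spec <- list(
    name = name,
    levels_assessment = levels_assessment,
    levels_training = levels_training,
    boundary = 0
  )
  class(spec) <- "dimension_spec"
  validate_dimension_spec(spec)
  spec
}

validate_dimension_spec <- function(spec) {
  la <- spec$levels_assessment
  if (length(la) != 7L || any(diff(la) <= 0) || any(la + rev(la) != 0)) {
    stop("assessment levels must be 7 strictly increasing values symmetric about 0")
  }
  if (length(spec$levels_training) != 50L) {
    stop("training continuum must contain exactly 50 levels")
  }
  if (spec$boundary != 0) stop("category boundary must sit at the dimension midpoint (0)")
  invisible(spec)
}

#' Sweep frequency-tagging trial design
#'
#' Constants of the sweep oddball paradigm: base stimulation at 6 Hz with a
#' 1.2 Hz oddball (every 5th image), 7 sweep steps of 10 s (12 oddball
#' presentations each), three trials per sweep direction, and a 1.67 s
#' fade-in/out flanking the 70 s stimulation core.
#'
#' @param base_freq Base stimulation frequency in Hz.
#' @param oddball_freq Oddball frequency in Hz.
#' @param n_steps Number of sweep steps per trial.
#' @param step_duration Step duration in seconds.
#' @param repeats_per_direction Trials per sweep direction.
#' @param fade_s Fade-in/out duration in seconds (outside the measured core).
#' @return A `sweep_design` object.
#' @export
sweep_design <- function(base_freq = 6, oddball_freq = 1.2, n_steps = 7,
                         step_duration = 10, repeats_per_direction = 3,
                         fade_s = 1.67) {
  ratio <- base_freq / oddball_freq
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("base_freq must be an integer multiple of oddball_freq")
  }
  pres <- step_duration * oddball_freq
  if (abs(pres - round(pres)) > 1e-9) {
    stop("step_duration must contain an integer number of oddball cycles")
  }
  design <- list(
    base_freq = base_freq,
    oddball_freq = oddball_freq,
    n_steps = n_steps,
    step_duration = step_duration,
    presentations_per_step = as.integer(round(pres)),
    fade_s = fade_s,
    directions = c("forward", "reverse"),
    repeats_per_direction = repeats_per_direction,
    size_jitter = c(-0.10, 0, 0.10),
    trial_duration = n_steps * step_duration
  )
  class(design) <- "sweep_design"
  design
}

#' Same-different discrimination task design
#'
#' Three "different" pairs along the assessment continuum -- pairs 1-3 and 5-7
#' within the (to be trained) categories and pair 3-5 across the boundary --
#' each shown in both screen orders, plus four identity ("same") pairs.  Each
#' of the 10 pair types is presented 20 times, organised in 4 blocks of 50
#' trials (5 presentations of each pair per block).
#'
#' @param repeats_per_pair Presentations of each pair type.
#' @param blocks Number of blocks.
#' @return A `discrimination_design` object.
#' @export
discrimination_design <- function(repeats_per_pair = 20, blocks = 4) {
  different <- list(c(1L, 3L), c(3L, 1L), c(5L, 7L), c(7L, 5L), c(3L, 5L), c(5L, 3L))
  same <- list(c(1L, 1L), c(3L, 3L), c(5L, 5L), c(7L, 7L))
  n_types <- length(different) + length(same)
  total <- n_types * repeats_per_pair
  if (total %% blocks != 0 || repeats_per_pair %% blocks != 0) {
    stop("repeats_per_pair must divide evenly over blocks")
  }
  design <- list(
    different_pairs = different,
    same_pairs = same,
    repeats_per_pair = as.integer(repeats_per_pair),
    blocks = as.integer(blocks),
    trials_per_block = as.integer(total %/% blocks),
    total_trials = as.integer(total),
    stim_duration_ms = 200,
    mask_duration_ms = 200
  )
  class(design) <- "discrimination_design"
  design
}

#' Category training task design
#'
#' Three blocks of 150 trials over the 50-level training continuum.  Block 1
#' shows every training stimulus three times; blocks 2 and 3 oversample the
#' boundary zone (the 20 stimuli closest to the category boundary) at 60/40
#' and 80/20 relative to the typical-exemplar zone.  Responses are later
#' aggregated into 10 trial bins of 15 trials and 10 stimulus bins of 5
#' adjacent stimuli.
#'
#' @param blocks Number of training blocks.
#' @param trials_per_block Trials per block.
#' @param boundary_fractions Per-block boundary-zone sampling fraction
#'   (`NA` for the uniform block).
#' @param boundary_zone_size Number of stimuli forming the boundary zone.
#' @param trial_bin_size Trials averaged per trial bin.
#' @param stimulus_bins Number of stimulus bins for psychometric fitting.
#' @return A `training_design` object.
#' @export
training_design <- function(blocks = 3, trials_per_block = 150,
                            boundary_fractions = c(NA, 0.60, 0.80),
                            boundary_zone_size = 20,
                            trial_bin_size = 15, stimulus_bins = 10) {
  if (length(boundary_fractions) != blocks) {
    stop("boundary_fractions must supply one entry per block")
  }
  bad <- !is.na(boundary_fractions) &
    (boundary_fractions <= 0 | boundary_fractions >= 1)
  if (any(bad)) stop("boundary-zone fractions must lie strictly in (0, 1)")
  if (trials_per_block %% trial_bin_size != 0) {
    stop("trials_per_block must divide into whole trial bins")
  }
  design <- list(
    blocks = as.integer(blocks),
    trials_per_block = as.integer(trials_per_block),
    total_trials = as.integer(blocks * trials_per_block),
    boundary_fractions = boundary_fractions,
    boundary_zone_size = boundary_zone_size,
    trial_bin_size = trial_bin_size,
    trial_bins = trials_per_block %/% trial_bin_size,
    stimulus_bins = stimulus_bins,
    pass_criterion = 0.50
  )
  class(design) <- "training_design"
  design
}

# Seeded pseudorandomisation: random permutation, then local repair swaps
# until no two consecutive entries share a key.  Deterministic under a seed;
# errors out on infeasible inputs.
no_repeat_shuffle <- function(x, key = x, seed = NULL, max_tries = 200L) {
  if (!is.null(seed)) seed <- as.integer(seed %% .Machine$integer.max)
  n <- length(x)
  do_shuffle <- function() {
    for (try in seq_len(max_tries)) {
      ord <- sample.int(n)
      k <- key[ord]
      ok <- TRUE
      for (pass in seq_len(50L)) {
        bad <- which(k[-1] == k[-n]) + 1L
        if (length(bad) == 0) break
        for (i in bad) {
          if (i > 1 && k[i] != k[i - 1]) next  # fixed by an earlier swap
          cand <- which(k != k[i])
          # j is acceptable if k[i] fits between j's neighbours and k[j]
          # fits between i's neighbours
          fits <- vapply(cand, function(j) {
            kj <- k[j]
            left_i <- if (i > 1) k[i - 1] else NA
            right_i <- if (i < n) k[i + 1] else NA
            left_j <- if (j > 1) k[j - 1] else NA
            right_j <- if (j < n) k[j + 1] else NA
            if (abs(j - i) == 1) return(FALSE)
            !identical(kj, left_i) && !identical(kj, right_i) &&
              !identical(k[i], left_j) && !identical(k[i], right_j)
          }, logical(1))
          cand <- cand[fits]
          if (length(cand) == 0) next
          j <- cand[sample.int(length(cand), 1)]
          tmp <- ord[i]; ord[i] <- ord[j]; ord[j] <- tmp
          tmp <- k[i]; k[i] <- k[j]; k[j] <- tmp
        }
      }
      if (!any(k[-1] == k[-n])) return(x[ord])
    }
    stop("could not arrange schedule without immediate repeats after ",
         max_tries, " shuffles")
  }
  if (is.null(seed)) do_shuffle() else with_rng(seed, do_shuffle())
}

# No-repeat shuffle whose first element must also differ from the last
# element of the preceding block (so blocks concatenate without repeats).
shuffle_avoiding <- function(x, seed, avoid_first = NA) {
  for (t in 0:49) {
    out <- no_repeat_shuffle(x, key = x, seed = seed + t * 7919L)
    if (is.na(avoid_first) || out[1] != avoid_first) return(out)
  }
  stop("could not open a block avoiding the previous block's final stimulus")
}

#' Build a sweep FT-EEG trial schedule
#'
#' Six 70 s sweep trials (three per direction, alternating).  Within a forward
#' trial the base stimulus is fixed at the +99% endpoint and the oddball
#' descends the 7 assessment levels starting identical to the base; reverse
#' trials mirror this from the -99% endpoint.
#'
#' @param design A [sweep_design()].
#' @param dimension A [dimension_spec()].
#' @param seed Integer seed (the schedule itself is deterministic; kept for a
#'   uniform schedule-builder interface).
#' @return A tibble with one row per trial x step: `trial`, `direction`,
#'   `step`, `base_level`, `oddball_level`, `dimension`.
#' @export
#' @examples
#' sched <- build_sweep_schedule(sweep_design(), dimension_spec("CR"), seed = 1)
#' subset(sched, step %in% c(1, 7) & trial == 1)
build_sweep_schedule <- function(design, dimension, seed = 1L) {
  levels <- dimension$levels_assessment
  if (design$n_steps != length(levels)) {
    stop("sweep design has ", design$n_steps, " steps but the dimension has ",
         length(levels), " assessment levels")
  }
  n_lev <- length(levels)
  n_trials <- 2L * design$repeats_per_direction
  directions <- rep(design$directions, design$repeats_per_direction)
  rows <- lapply(seq_len(n_trials), function(tr) {
    dir <- directions[tr]
    if (dir == "forward") {
      base <- levels[n_lev]
      odd <- levels[n_lev + 1L - seq_len(design$n_steps)]
    } else {
      base <- levels[1L]
      odd <- levels[seq_len(design$n_steps)]
    }
    tibble::tibble(
      trial = tr, direction = dir, step = seq_len(design$n_steps),
      base_level = base, oddball_level = odd
    )
  })
  out <- dplyr::bind_rows(rows)
  out$dimension <- dimension$name
  out
}

#' Build a same-different discrimination schedule
#'
#' Pseudorandomised (seeded rejection shuffle) so that no two consecutive
#' trials are identical; each block contains 5 presentations of each of the
#' 10 pair types.
#'
#' @param design A [discrimination_design()].
#' @param seed Integer seed.
#' @return A tibble with `trial`, `block`, `pair_type`, `idx_left`,
#'   `idx_right`, `is_same`.
#' @export
build_discrimination_schedule <- function(design, seed = 1L) {
  pairs <- c(design$different_pairs, design$same_pairs)
  is_same <- c(rep(FALSE, length(design$different_pairs)),
               rep(TRUE, length(design$same_pairs)))
  type_label <- vapply(seq_along(pairs), function(i) {
    p <- sort(pairs[[i]])
    if (is_same[i]) paste0("same_", p[1]) else pair_type_label(p)
  }, character(1))
  per_block <- design$repeats_per_pair %/% design$blocks
  blocks <- vector("list", design$blocks)
  prev_last <- NA_integer_
  for (b in seq_len(design$blocks)) {
    ids <- rep(seq_along(pairs), each = per_block)
    ids <- shuffle_avoiding(ids, seed = seed * 131L + b, avoid_first = prev_last)
    prev_last <- ids[length(ids)]
    blocks[[b]] <- tibble::tibble(
      block = b,
      pair_type = type_label[ids],
      idx_left = vapply(pairs[ids], `[`, integer(1), 1L),
      idx_right = vapply(pairs[ids], `[`, integer(1), 2L),
      is_same = is_same[ids]
    )
  }
  out <- dplyr::bind_rows(blocks)
  out$trial <- seq_len(nrow(out))
  dplyr::relocate(out, "trial")
}

pair_type_label <- function(sorted_pair) {
  if (identical(sorted_pair, c(3L, 5L))) "between_35"
  else paste0("within_", sorted_pair[1], sorted_pair[2])
}

#' Build a category-training schedule
#'
#' Block 1 presents each of the 50 training stimuli exactly three times;
#' blocks 2 and 3 draw boundary-zone versus typical-zone stimuli at the
#' design's 60/40 and 80/20 fractions (deterministic zone counts, stimuli
#' within a zone allocated as evenly as possible with seeded remainders).
#' No stimulus repeats immediately.
#'
#' @param design A [training_design()].
#' @param dimension A [dimension_spec()].
#' @param seed Integer seed.
#' @return A tibble with `trial`, `block`, `level` (signed percent),
#'   `stimulus` (index 1..50), `category` ("A" below boundary, "B" above) and
#'   `boundary_zone` flag.
#' @export
build_training_schedule <- function(design, dimension, seed = 1L) {
  levels <- dimension$levels_training
  n_stim <- length(levels)
  dist <- abs(levels - dimension$boundary)
  zone_idx <- order(dist)[seq_len(design$boundary_zone_size)]
  in_zone <- seq_len(n_stim) %in% zone_idx
  blocks <- vector("list", design$blocks)
  prev_last <- NA_integer_
  for (b in seq_len(design$blocks)) {
    frac <- design$boundary_fractions[b]
    if (is.na(frac)) {
      reps <- design$trials_per_block / n_stim
      if (reps != round(reps)) stop("uniform block size must divide the stimulus count")
      stim <- rep(seq_len(n_stim), each = reps)
    } else {
      n_zone <- round(frac * design$trials_per_block)
      stim <- c(
        allocate_evenly(which(in_zone), n_zone, seed = seed * 977L + 2L * b),
        allocate_evenly(which(!in_zone), design$trials_per_block - n_zone,
                        seed = seed * 977L + 2L * b + 1L)
      )
    }
    stim <- shuffle_avoiding(stim, seed = seed * 977L + 100L + b,
                             avoid_first = prev_last)
    prev_last <- stim[length(stim)]
    blocks[[b]] <- tibble::tibble(block = b, stimulus = stim)
  }
  out <- dplyr::bind_rows(blocks)
  out$trial <- seq_len(nrow(out))
  out$level <- levels[out$stimulus]
  out$category <- ifelse(out$level > dimension$boundary, "B", "A")
  out$boundary_zone <- in_zone[out$stimulus]
  dplyr::relocate(out, "trial", "block", "stimulus", "level")
}

# Spread n draws over the given stimulus indices: floor(n/k) each plus a
# seeded sample (without replacement) receiving one extra.
allocate_evenly <- function(idx, n, seed) {
  seed <- as.integer(seed %% .Machine$integer.max)
  k <- length(idx)
  base <- n %/% k
  extra <- n - base * k
  counts <- rep(base, k)
  if (extra > 0) {
    who <- with_rng(seed, sample.int(k, extra))
    counts[who] <- counts[who] + 1L
  }
  rep(idx, counts)
}

#' Assign training stimuli to stimulus bins
#'
#' Maps the 50 training levels onto 10 bins of 5 adjacent levels, in level
#' order.  Returns a tibble of `stimulus`, `level`, `bin`, `bin_center`.
#'
#' @param dimension A [dimension_spec()].
#' @param n_bins Number of stimulus bins.
#' @export
stimulus_bin_map <- function(dimension, n_bins = 10) {
  levels <- sort(dimension$levels_training)
  n <- length(levels)
  if (n %% n_bins != 0) stop("training levels must divide evenly into bins")
  per <- n %/% n_bins
  bin <- rep(seq_len(n_bins), each = per)
  centers <- tapply(levels, bin, mean)
  tibble::tibble(
    stimulus = seq_len(n), level = levels, bin = bin,
    bin_center = as.numeric(centers[bin])
  )
}

#' Write / read a trial schedule as CSV
#'
#' Schedules round-trip losslessly through plain CSV.
#'
#' @param schedule A schedule tibble.
#' @param path File path.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_csv(schedule, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
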