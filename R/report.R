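#' Pipeline run configuration
#'
#' Bundles the design objects, generative scenario and cohort size of an
#' end-to-end simulate-quantify-analyse run.  Seeds are explicit: every
#' random draw in the run derives deterministically from `seed`.
#'
#' @param n_subjects Subjects per group.
#' @param seed Master seed.
#' @param scenarios Per-group generative scenario, see [group_scenarios()].
#' @param dimension A [dimension_spec()] (dimension assignment is shared by
#'   all simulated subjects of a run).
#' @param sweep,discrimination,training Design objects.
#' @param pre_cfg,spec_cfg Quantification configurations.
#' @param rois ROI channel sets.
#' @param neural Simulate and quantify EEG (the expensive stage); disable
#'   for behavior-only runs.
#' @param neural_model_args Overrides passed to [neural_gen_model()]
#'   (tuning is supplied per group x moment by the scenario).
#' @return A `run_config`.
#' @export
run_config <- function(n_subjects = 4, seed = 1L, scenarios = group_scenarios(),
                       dimension = dimension_spec("CR"),
                       sweep = sweep_design(),
                       discrimination = discrimination_design(),
                       training = training_design(),
                       pre_cfg = preproc_config(), spec_cfg = spectrum_config(),
                       rois = default_rois(), neural = TRUE,
                       neural_model_args = list()) {
  if (seed >= 2^31 / 1e6) stop("seed too large for derived per-subject seeds")
  cfg <- list(
    n_subjects = n_subjects, seed = as.integer(seed), scenarios = scenarios,
    dimension = dimension, sweep = sweep, discrimination = discrimination,
    training = training, pre_cfg = pre_cfg, spec_cfg = spec_cfg, rois = rois,
    neural = neural, neural_model_args = neural_model_args
  )
  class(cfg) <- "run_config"
  cfg
}

# deterministic per-subject/stage seed derivation (stays below 2^31)
derive_seed <- function(seed, subject_id, stage) {
  (seed * 1e6 + subject_id * 131L + stage) %% .Machine$integer.max
}

#' Run the full simulate - quantify - analyse pipeline
#'
#' For every simulated subject: generate sweep EEG recordings for both
#' assessment moments under the subject's group scenario and quantify them;
#' generate discrimination responses pre and post and compute per-pair d'
#' and the categorical-perception index; generate training responses,
#' bin them and fit the psychometric function per block.  All tables are
#' written as CSV to `out_dir` together with a machine-readable manifest
#' (inputs, seeds, file checksums).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list of the result tibbles plus the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  quant <- list()
  dpr <- list()
  cpi <- list()
  fits <- list()
  tbins <- list()
  subject_id <- 0L
  for (grp in names(config$scenarios)) {
    scen <- config$scenarios[[grp]]
    for (s in seq_len(config$n_subjects)) {
      subject_id <- subject_id + 1L
      subj <- sprintf("%s%02d", tolower(grp), s)
      # --- behavior: discrimination pre/post
      for (moment in c("pre", "post")) {
        sched <- build_discrimination_schedule(
          config$discrimination,
          seed = derive_seed(config$seed, subject_id, if (moment == "pre") 1L else 2L)
        )
        resp <- simulate_discrimination_responses(
          scen$behavior, sched, moment = moment,
          seed = derive_seed(config$seed, subject_id, if (moment == "pre") 3L else 4L)
        )
        resp$subject <- subj
        resp$group <- grp
        resp$dimension <- config$dimension$name
        dd <- dprime_by_pair(resp)
        dpr[[length(dpr) + 1L]] <- dd
        cpi[[length(cpi) + 1L]] <- tibble::tibble(
          subject = subj, group = grp, dimension = config$dimension$name,
          moment = moment, cp_index = cp_contrast(dd)
        )
      }
      # --- behavior: training
      tsched <- build_training_schedule(
        config$training, config$dimension,
        seed = derive_seed(config$seed, subject_id, 5L)
      )
      tresp <- simulate_training_responses(
        scen$behavior, tsched, seed = derive_seed(config$seed, subject_id, 6L)
      )
      binned <- bin_training(tresp, config$training, config$dimension)
      tb <- binned$trial_bins
      tb$subject <- subj
      tb$group <- grp
      tbins[[length(tbins) + 1L]] <- tb
      for (b in sort(unique(binned$stimulus_bins$block))) {
        ft <- fit_psychometric(
          binned$stimulus_bins[binned$stimulus_bins$block == b, ],
          seed = derive_seed(config$seed, subject_id, 10L + b)
        )
        ft$subject <- subj
        ft$group <- grp
        ft$block <- b
        ft$gen_slope <- tresp$gen_slope[match(b, tresp$block)]
        ft$gen_threshold <- tresp$gen_threshold[1]
        fits[[length(fits) + 1L]] <- ft
      }
      # --- neural: sweep EEG pre/post
      if (config$neural) {
        for (moment in c("pre", "post")) {
          margs <- config$neural_model_args
          margs$tuning <- scen$tuning[[moment]]
          model <- do.call(neural_gen_model, margs)
          ssched <- build_sweep_schedule(config$sweep, config$dimension)
          rec <- simulate_sweep_recording(
            model, ssched, config$sweep,
            seed = derive_seed(config$seed, subject_id, if (moment == "pre") 20L else 21L)
          )
          q <- quantify_recording(rec, config$sweep, config$pre_cfg,
                                  config$spec_cfg, config$rois)
          q$subject <- subj
          q$group <- grp
          q$dimension <- config$dimension$name
          q$moment <- moment
          quant[[length(quant) + 1L]] <- q
          rm(rec)
        }
      }
    }
  }
  results <- list(
    dprime = dplyr::bind_rows(dpr),
    cp_index = dplyr::bind_rows(cpi),
    psychometric_fits = dplyr::bind_rows(fits),
    trial_bins = dplyr::bind_rows(tbins)
  )
  if (config$neural) results$quantification <- dplyr::bind_rows(quant)
  contrasts <- make_contrast_tables(results$quantification, results$dprime)
  results <- c(results, contrasts)
  files <- character()
  for (nm in names(results)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(results[[nm]], path)
    files <- c(files, path)
  }
  manifest <- list(
    seed = config$seed, n_subjects = config$n_subjects,
    groups = names(config$scenarios), dimension = config$dimension$name,
    neural = config$neural,
    files = lapply(setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  writeLines(to_json(manifest), manifest_path)
  results$manifest <- manifest
  invisible(results)
}

# minimal JSON writer (scalars, named lists, character/numeric vectors)
to_json <- function(x, indent = "") {
  if (is.list(x)) {
    inner <- vapply(names(x), function(nm) {
      sprintf("%s  \"%s\": %s", indent, nm, to_json(x[[nm]], paste0(indent, "  ")))
    }, character(1))
    paste0("{\n", paste(inner, collapse = ",\n"), "\n", indent, "}")
  } else if (length(x) == 1) {
    if (is.character(x)) sprintf("\"%s\"", x)
    else if (is.logical(x)) tolower(as.character(x))
    else format(x, digits = 15)
  } else {
    elems <- vapply(x, function(e) to_json(e), character(1))
    paste0("[", paste(elems, collapse = ", "), "]")
  }
}

#' Assemble tidy contrast tables for external model fitting
#'
#' Long-format tables keyed the way the statistical contrasts are defined:
#' the neural table restricted to the analysis sweep steps (2, 4, 6:
#' within / boundary / within) by ROI, and the behavioral d' table by
#' within- versus between-category comparison.  Extreme outliers (beyond
#' `Q3 + 3 IQR` or below `Q1 - 3 IQR`, linear-interpolation quartiles) are
#' flagged per measure, never dropped.
#'
#' @param quantification Output of [sweep_quantification()] /
#'   [run_pipeline()] (or NULL).
#' @param dprimes Output of [dprime_by_pair()] (or NULL).
#' @return A list with `neural_contrasts` and/or `behavior_contrasts`.
#' @export
make_contrast_tables <- function(quantification = NULL, dprimes = NULL) {
  out <- list()
  if (!is.null(quantification)) {
    nc <- quantification[quantification$is_contrast_step &
                           quantification$roi %in% c("LOT", "ROT"), ]
    nc <- nc[, intersect(c("subject", "group", "dimension", "moment", "roi",
                           "step", "oddball_sum", "base_sum"), names(nc))]
    nc$contrast <- ifelse(nc$step == 4, "boundary", "within")
    nc$extreme_outlier <- flag_extreme_outliers(nc$oddball_sum)
    out$neural_contrasts <- tibble::as_tibble(nc)
  }
  if (!is.null(dprimes)) {
    bc <- dprimes
    bc$comparison <- ifelse(bc$pair_type == "between_35", "between", "within")
    bc$extreme_outlier <- flag_extreme_outliers(bc$dprime)
    out$behavior_contrasts <- tibble::as_tibble(bc)
  }
  out
}

#' Flag extreme outliers by the 3 x IQR fence
#'
#' Values above `Q3 + 3 IQR` or below `Q1 - 3 IQR` (type-7 quartiles) are
#' flagged; nothing is removed.
#'
#' @param x Numeric vector.
#' @return Logical vector (NA values flag as NA).
#' @export
flag_extreme_outliers <- function(x) {
  q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7)
  iqr <- q[2] - q[1]
  x > q[2] + 3 * iqr | x < q[1] - 3 * iqr
}

#' Per-step oddball amplitude figure
#'
#' Mean summed baseline-corrected oddball amplitude per sweep step, by group
#' and assessment moment (occipito-temporal ROIs averaged).
#'
#' @param quantification Quantification table with `subject`, `group`,
#'   `moment`, `roi`, `step`, `oddball_sum`.
#' @return A ggplot object.
#' @export
plot_sweep_amplitudes <- function(quantification) {
  dat <- quantification[quantification$roi %in% c("LOT", "ROT"), ] |>
    dplyr::group_by(.data$group, .data$moment, .data$step) |>
    dplyr::summarise(amplitude = mean(.data$oddball_sum), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(.data$step, .data$amplitude,
                                    colour = .data$moment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 4, linetype = "dashed") +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_x_continuous(breaks = 1:7) +
    ggplot2::labs(x = "Sweep step", y = "Summed oddball amplitude (µV)",
                  colour = "Assessment") +
    ggplot2::theme_minimal()
}

#' Per-pair d-prime figure
#'
#' @param dprimes Output of [dprime_by_pair()] with `group` and `moment`.
#' @return A ggplot object.
#' @export
plot_dprime_pairs <- function(dprimes) {
  dat <- dprimes |>
    dplyr::group_by(.data$group, .data$moment, .data$pair_type) |>
    dplyr::summarise(dprime = mean(.data$dprime), .groups = "drop")
  dat$pair_type <- factor(dat$pair_type,
                          levels = c("within_13", "between_35", "within_57"))
  ggplot2::ggplot(dat, ggplot2::aes(.data$pair_type, .data$dprime,
                                    group = .data$moment,
                                    colour = .data$moment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "Stimulus pair", y = "d'", colour = "Assessment") +
    ggplot2::theme_minimal()
}

#' Fitted psychometric curves figure
#'
#' @param stimulus_bins Binned category responses (`bin_center`, `prop_b`,
#'   `block`).
#' @param fits Per-block [fit_psychometric()] results.
#' @return A ggplot object.
#' @export
plot_psychometric <- function(stimulus_bins, fits) {
  grid <- do.call(rbind, lapply(seq_len(nrow(fits)), function(i) {
    x <- seq(min(stimulus_bins$bin_center), max(stimulus_bins$bin_center),
             length.out = 101)
    data.frame(block = fits$block[i], x = x,
               p = 1 / (1 + exp(-fits$slope[i] * (x - fits$threshold[i]))))
  }))
  ggplot2::ggplot(stimulus_bins,
                  ggplot2::aes(.data$bin_center, .data$prop_b)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$x, .data$p)) +
    ggplot2::facet_wrap(~block, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Stimulus level (%)", y = "P(category B)") +
    ggplot2::theme_minimal()
}
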