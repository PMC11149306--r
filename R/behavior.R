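#' Sensitivity index d-prime from hit / false-alarm counts
#'
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)` for a same-different
#' design, where hits are "different" responses on different pairs and false
#' alarms are "different" responses on same pairs.  Extreme proportions (0
#' or 1) are replaced by `1/(2N)` and `1 - 1/(2N)` so the index stays
#' finite.
#'
#' @param n_hits "Different" responses on different-pair trials.
#' @param n_different Number of different-pair trials.
#' @param n_fa "Different" responses on same-pair trials.
#' @param n_same Number of same-pair trials.
#' @param correct_extremes Apply the 1/(2N) extreme-proportion correction.
#' @return A one-row tibble: `hit_rate`, `fa_rate`, `dprime`, `n_different`,
#'   `n_same`.
#' @export
#' @examples
#' dprime(69, 100, 31, 100)$dprime  # ~ 0.99
dprime <- function(n_hits, n_different, n_fa, n_same, correct_extremes = TRUE) {
  if (n_different <= 0 || n_same <= 0) stop("trial counts must be positive")
  if (n_hits < 0 || n_fa < 0 || n_hits > n_different || n_fa > n_same) {
    stop("response counts must lie within their trial counts")
  }
  clamp <- function(k, n) {
    p <- k / n
    if (correct_extremes) {
      p <- min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
    } else if (p %in% c(0, 1)) {
      stop("extreme proportion with correction disabled")
    }
    p
  }
  hit <- clamp(n_hits, n_different)
  fa <- clamp(n_fa, n_same)
  tibble::tibble(
    hit_rate = hit, fa_rate = fa, dprime = qnorm(hit) - qnorm(fa),
    n_different = n_different, n_same = n_same
  )
}

#' Per-pair d-prime table from discrimination trials
#'
#' Computes d' for each different-pair type against the false-alarm rate
#' pooled over all same pairs, per block (and any further grouping columns
#' present, e.g. subject / moment).
#'
#' @param trials A trial table from [simulate_discrimination_responses()]
#'   (columns `pair_type`, `is_same`, `response`, `block`).
#' @param by Extra grouping columns.
#' @return A tidy tibble with one row per group x block x pair type.
#' @export
dprime_by_pair <- function(trials, by = intersect(c("subject", "group", "moment",
                                                    "dimension"), names(trials))) {
  groups <- c(by, "block")
  split_keys <- interaction(trials[groups], drop = TRUE)
  dplyr::bind_rows(lapply(split(trials, split_keys), function(tt) {
    n_fa <- sum(tt$is_same & tt$response == "different")
    n_same <- sum(tt$is_same)
    diffs <- tt[!tt$is_same, ]
    dplyr::bind_rows(lapply(split(diffs, diffs$pair_type), function(pp) {
      res <- dprime(sum(pp$response == "different"), nrow(pp), n_fa, n_same)
      meta <- pp[1, groups, drop = FALSE]
      meta$pair_type <- pp$pair_type[1]
      dplyr::bind_cols(meta, res)
    }))
  }))
}

#' Categorical-perception contrast
#'
#' Between-category d' minus the unweighted mean of the two within-category
#' d' values; positive values indicate a discrimination peak at the category
#' boundary.
#'
#' @param dprimes A tibble with `pair_type` and `dprime` columns containing
#'   the three different-pair types (`within_13`, `within_57`,
#'   `between_35`); multiple rows per pair type (e.g. blocks) are averaged
#'   first.
#' @return Scalar CP index.
#' @export
cp_contrast <- function(dprimes) {
  need <- c("within_13", "within_57", "between_35")
  missing <- setdiff(need, dprimes$pair_type)
  if (length(missing)) {
    stop("missing pair type(s): ", paste(missing, collapse = ", "))
  }
  m <- tapply(dprimes$dprime, dprimes$pair_type, mean)
  unname(m["between_35"] - (m["within_13"] + m["within_57"]) / 2)
}

#' Bin training trials into trial bins and stimulus bins
#'
#' Trial bins: consecutive groups of `trial_bin_size` trials per block (10
#' bins of 15 trials under the default design), with mean accuracy and RT.
#' Stimulus bins: the 50 training levels mapped onto 10 bins of 5 adjacent
#' levels, with the proportion of category-"B" responses and the response
#' count per bin per block (15 responses per bin in the uniform block).
#'
#' @param trials A trial table from [simulate_training_responses()].
#' @param design The [training_design()].
#' @param dimension The [dimension_spec()].
#' @param rt_correct_only Average RTs over correct trials only (default all
#'   trials; training feedback makes error RTs meaningful).
#' @return A list with tibbles `trial_bins` and `stimulus_bins`.
#' @export
bin_training <- function(trials, design = training_design(),
                         dimension = dimension_spec("CR"),
                         rt_correct_only = FALSE) {
  per_block <- table(trials$block)
  if (any(per_block %% design$trial_bin_size != 0)) {
    stop("trials per block must divide into whole trial bins of ",
         design$trial_bin_size)
  }
  trials <- trials[order(trials$trial), ]
  trial_bins <- trials |>
    dplyr::group_by(.data$block) |>
    dplyr::mutate(trial_bin = (dplyr::row_number() - 1L) %/% design$trial_bin_size + 1L) |>
    dplyr::group_by(.data$block, .data$trial_bin) |>
    dplyr::summarise(
      accuracy = mean(.data$correct),
      rt = if (rt_correct_only) mean(.data$rt[.data$correct]) else mean(.data$rt),
      n = dplyr::n(), .groups = "drop"
    )
  bins <- stimulus_bin_map(dimension, design$stimulus_bins)
  trials$stim_bin <- bins$bin[match(trials$level, bins$level)]
  trials$bin_center <- bins$bin_center[match(trials$level, bins$level)]
  stimulus_bins <- trials |>
    dplyr::group_by(.data$block, .data$stim_bin, .data$bin_center) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_b = sum(.data$response == "B"),
      prop_b = mean(.data$response == "B"),
      .groups = "drop"
    )
  list(trial_bins = trial_bins, stimulus_bins = stimulus_bins)
}

#' Fit a logistic psychometric function to binned category responses
#'
#' Maximum binomial likelihood fit of
#' `p(x) = 1 / (1 + exp(-(x - threshold) / beta_scale))` via the binomial
#' GLM with logit link; the threshold is the stimulus level at p = 0.5 (the
#' fitted category boundary) and the reported `slope` is the steepness
#' `1/beta_scale` (larger = sharper boundary).  Confidence intervals come
#' from a seeded parametric bootstrap.  Degenerate data (no response
#' variation) yield a non-converged result rather than an error.
#'
#' @param bins A tibble with `bin_center` (or `x`), `n_b` (category-"B"
#'   count) and `n` per bin.
#' @param n_boot Parametric bootstrap replicates for the 95% CIs.
#' @param seed Bootstrap seed.
#' @param conf_level Confidence level.
#' @return A one-row tibble: `threshold`, `slope`, `beta_scale`,
#'   `threshold_lo/hi`, `slope_lo/hi`, `loglik`, `converged`.
#' @export
fit_psychometric <- function(bins, n_boot = 200, seed = 1L, conf_level = 0.95) {
  x <- if ("bin_center" %in% names(bins)) bins$bin_center else bins$x
  k <- bins$n_b
  n <- bins$n
  if (length(x) < 4) stop("need at least 4 bins with responses")
  failed <- tibble::tibble(
    threshold = NA_real_, slope = NA_real_, beta_scale = NA_real_,
    threshold_lo = NA_real_, threshold_hi = NA_real_,
    slope_lo = NA_real_, slope_hi = NA_real_,
    loglik = NA_real_, converged = FALSE
  )
  if (all(k == 0) || all(k == n)) return(failed)
  core_fit <- function(k_i) {
    fit <- suppressWarnings(glm(cbind(k_i, n - k_i) ~ x, family = binomial()))
    b <- coef(fit)
    c(threshold = unname(-b[1] / b[2]), slope = unname(b[2]),
      loglik = as.numeric(stats::logLik(fit)), converged = fit$converged)
  }
  est <- tryCatch(core_fit(k), error = function(e) NULL)
  if (is.null(est) || !is.finite(est["slope"]) || est["slope"] <= 0 ||
      !est["converged"]) {
    return(failed)
  }
  if (n_boot == 0) {
    return(tibble::tibble(
      threshold = est[["threshold"]], slope = est[["slope"]],
      beta_scale = 1 / est[["slope"]],
      threshold_lo = NA_real_, threshold_hi = NA_real_,
      slope_lo = NA_real_, slope_hi = NA_real_,
      loglik = est[["loglik"]], converged = TRUE
    ))
  }
  p_hat <- 1 / (1 + exp(-est["slope"] * (x - est["threshold"])))
  boot <- with_rng(seed, {
    t(replicate(n_boot, {
      kk <- rbinom(length(n), n, p_hat)
      out <- tryCatch(core_fit(kk), error = function(e) rep(NA_real_, 4))
      out[c("threshold", "slope")]
    }))
  })
  a <- (1 - conf_level) / 2
  ci <- apply(boot, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE)
  tibble::tibble(
    threshold = est[["threshold"]], slope = est[["slope"]],
    beta_scale = 1 / est[["slope"]],
    threshold_lo = ci[1, 1], threshold_hi = ci[2, 1],
    slope_lo = ci[1, 2], slope_hi = ci[2, 2],
    loglik = est[["loglik"]], converged = TRUE
  )
}

#' Two-sample variance-ratio (F) test
#'
#' `F = var(a) / var(b)` with `(n_a - 1, n_b - 1)` degrees of freedom and a
#' two-sided p-value from the F distribution, as used to compare
#' between-subject slope variability across groups.
#'
#' @param a,b Numeric vectors (at least 2 values each).
#' @return A one-row tibble: `f`, `df1`, `df2`, `p`.
#' @export
variance_ratio_test <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per group")
  if (var(b) == 0) stop("zero variance in the denominator group")
  ht <- var.test(a, b)
  tibble::tibble(
    f = unname(ht$statistic),
    df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]),
    p = ht$p.value
  )
}

#' Pearson correlation of a per-subject measure with trait scores
#'
#' @param measure,traits Paired numeric vectors; incomplete pairs are
#'   dropped.
#' @return A one-row tibble: `r`, `p`, `n`.
#' @export
correlate_with_traits <- function(measure, traits) {
  keep <- is.finite(measure) & is.finite(traits)
  x <- measure[keep]
  y <- traits[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: correlation undefined")
  ht <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Power of the variance-ratio test
#'
#' Closed-form power for detecting a true variance ratio with a two-sided F
#' test at the given sample sizes.
#'
#' @param ratio True variance ratio var(a)/var(b).
#' @param n_a,n_b Group sizes.
#' @param alpha Two-sided significance level.
#' @return Scalar power.
#' @export
variance_ratio_power <- function(ratio, n_a, n_b, alpha = 0.05) {
  df1 <- n_a - 1
  df2 <- n_b - 1
  lo <- stats::qf(alpha / 2, df1, df2)
  hi <- stats::qf(1 - alpha / 2, df1, df2)
  pf(lo / ratio, df1, df2) + pf(hi / ratio, df1, df2, lower.tail = FALSE)
}
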