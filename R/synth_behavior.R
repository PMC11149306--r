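#' Generative model for behavioral observers
#'
#' Signal-detection observer for the same-different discrimination task and
#' a logistic learner for the category training task.  The default group
#' scenarios encode the qualitative structure the analysis is built to
#' detect: the neurotypical (NT) observer is more sensitive to the
#' between-category pair than to within-category pairs at both assessment
#' moments, whereas the autistic (ASC) observer starts with equal
#' sensitivities and acquires the between-category advantage only after
#' training; the ASC learner's block-1 psychometric slope is more variable
#' between subjects.  These are scenario parameters, not estimates of the
#' study's effect sizes.
#'
#' @param dprime Named list of per-moment sensitivities, each a list with
#'   elements `within` and `between`.
#' @param criterion Response criterion c of the equal-variance Gaussian
#'   observer (positive = conservative, biased to "same").
#' @param lapse Lapse rate mixed into every response.
#' @param rt_shift,rt_meanlog,rt_sdlog Shifted-lognormal RT parameters (s).
#' @param slope_mean Per-block mean psychometric slope (probability per
#'   percent; the logistic steepness 1/beta-scale).
#' @param slope_sd Per-block between-subject SD of the slope; element 1 is
#'   the group's initial-block heterogeneity.
#' @param threshold_sd Between-subject SD of the category boundary location
#'   (percent).
#' @return A `behavioral_gen_model`.
#' @export
behavioral_gen_model <- function(dprime = list(pre = list(within = 1.0, between = 2.0),
                                               post = list(within = 1.3, between = 2.3)),
                                 criterion = 0.2, lapse = 0.02,
                                 rt_shift = 0.25, rt_meanlog = -0.55, rt_sdlog = 0.30,
                                 slope_mean = c(0.06, 0.10, 0.14),
                                 slope_sd = c(0.015, 0.02, 0.02),
                                 threshold_sd = 6) {
  stopifnot(length(slope_mean) == length(slope_sd))
  dvals <- unlist(dprime)
  if (any(dvals < 0)) stop("d-prime parameters must be non-negative")
  if (lapse < 0 || lapse >= 0.5) stop("lapse must lie in [0, 0.5)")
  model <- list(
    dprime = dprime, criterion = criterion, lapse = lapse,
    rt_shift = rt_shift, rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
    slope_mean = slope_mean, slope_sd = slope_sd, threshold_sd = threshold_sd
  )
  class(model) <- "behavioral_gen_model"
  model
}

#' Default two-group scenario
#'
#' Behavioral and neural generative parameters per group: NT shows the
#' between-category sensitivity advantage at both moments and categorical
#' oddball tuning pre and post; ASC starts without either and acquires both
#' after training, with 1.8-fold larger block-1 slope heterogeneity.
#'
#' @return A named list with one entry per group (`NT`, `ASC`), each holding
#'   `behavior` (a [behavioral_gen_model()]) and `tuning` (per-moment oddball
#'   tuning curves).
#' @export
group_scenarios <- function() {
  list(
    NT = list(
      behavior = behavioral_gen_model(
        dprime = list(pre = list(within = 1.0, between = 2.0),
                      post = list(within = 1.3, between = 2.3)),
        slope_sd = c(0.015, 0.02, 0.02)
      ),
      tuning = list(pre = default_tuning("categorical"),
                    post = default_tuning("categorical"))
    ),
    ASC = list(
      behavior = behavioral_gen_model(
        dprime = list(pre = list(within = 0.8, between = 0.8),
                      post = list(within = 0.9, between = 1.9)),
        slope_sd = c(0.027, 0.02, 0.02)
      ),
      tuning = list(pre = default_tuning("linear"),
                    post = default_tuning("categorical"))
    )
  )
}

#' Simulate same-different discrimination responses
#'
#' Equal-variance Gaussian observer: "different" responses occur with
#' probability `Phi(d'/2 - c)` on different pairs and `Phi(-d'/2 - c)` on
#' same pairs, with the pair-type d' (within/between) for different pairs
#' and the mean of the two for the same-pair decision variable, mixed with a
#' lapse rate; RTs are shifted lognormal.
#'
#' @param model A [behavioral_gen_model()].
#' @param schedule A discrimination schedule from
#'   [build_discrimination_schedule()].
#' @param moment `"pre"` or `"post"`.
#' @param seed Integer seed.
#' @return The schedule with `response` ("different"/"same"), `correct` and
#'   `rt` columns appended.
#' @export
simulate_discrimination_responses <- function(model, schedule,
                                              moment = c("pre", "post"),
                                              seed = 1L) {
  moment <- match.arg(moment)
  dpar <- model$dprime[[moment]]
  d_for <- function(pair_type) {
    if (grepl("^within_", pair_type)) dpar$within
    else if (pair_type == "between_35") dpar$between
    else if (grepl("^same_", pair_type)) (dpar$within + dpar$between) / 2
    else stop("unknown pair type: ", pair_type)
  }
  d <- vapply(schedule$pair_type, d_for, numeric(1))
  p_diff <- ifelse(schedule$is_same,
                   pnorm(-d / 2 - model$criterion),
                   pnorm(d / 2 - model$criterion))
  p_diff <- model$lapse / 2 + (1 - model$lapse) * p_diff
  with_rng(seed, {
    said_diff <- runif(nrow(schedule)) < p_diff
    rt <- model$rt_shift + rlnorm(nrow(schedule), model$rt_meanlog, model$rt_sdlog)
  })
  out <- schedule
  out$response <- ifelse(said_diff, "different", "same")
  out$correct <- said_diff != out$is_same
  out$rt <- rt
  out$moment <- moment
  out
}

#' Simulate category-training responses
#'
#' Each simulated subject owns a category boundary drawn around the true
#' boundary and a per-block psychometric slope drawn from the group's slope
#' distribution (steepening across blocks per `slope_mean`).  The
#' probability of a category-"B" response follows the logistic
#' `lapse/2 + (1 - lapse) / (1 + exp(-slope * (level - threshold)))`.
#'
#' @param model A [behavioral_gen_model()].
#' @param schedule A training schedule from [build_training_schedule()].
#' @param seed Integer seed.
#' @return The schedule with `response` ("A"/"B"), `correct`, `rt`, and the
#'   subject's generative `gen_threshold` and per-block `gen_slope`.
#' @export
simulate_training_responses <- function(model, schedule, seed = 1L) {
  n_blocks <- max(schedule$block)
  if (length(model$slope_mean) < n_blocks) {
    stop("model supplies slopes for ", length(model$slope_mean),
         " blocks but the schedule has ", n_blocks)
  }
  with_rng(seed, {
    thr <- rnorm(1, 0, model$threshold_sd)
    slopes <- pmax(rnorm(n_blocks, model$slope_mean[seq_len(n_blocks)],
                         model$slope_sd[seq_len(n_blocks)]), 1e-3)
    p_b <- model$lapse / 2 + (1 - model$lapse) /
      (1 + exp(-slopes[schedule$block] * (schedule$level - thr)))
    said_b <- runif(nrow(schedule)) < p_b
    rt <- model$rt_shift + rlnorm(nrow(schedule), model$rt_meanlog, model$rt_sdlog)
  })
  out <- schedule
  out$response <- ifelse(said_b, "B", "A")
  out$correct <- out$response == out$category
  out$rt <- rt
  out$gen_threshold <- thr
  out$gen_slope <- slopes[out$block]
  out
}
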