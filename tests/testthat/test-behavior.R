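test_that("d-prime matches the inverse-normal oracle", {
  expect_equal(dprime(69, 100, 31, 100)$dprime,
               qnorm(0.69) - qnorm(0.31), tolerance = 1e-12)
  expect_equal(dprime(69, 100, 31, 100)$dprime, 0.99, tolerance = 0.01)
  # equal rates give zero, antisymmetry under swapping hits and false alarms
  expect_equal(dprime(30, 100, 30, 100)$dprime, 0)
  expect_equal(dprime(80, 100, 20, 100)$dprime,
               -dprime(20, 100, 80, 100)$dprime)
  # perfect hits with the 1/(2N) correction: 20/20 -> 0.975
  res <- dprime(20, 20, 10, 20)
  expect_equal(res$hit_rate, 0.975)
  expect_equal(res$dprime, qnorm(0.975), tolerance = 1e-12)
  expect_error(dprime(5, 0, 1, 10), "positive")
  expect_error(dprime(5, 10, 1, 10, correct_extremes = FALSE), NA)
  expect_error(dprime(10, 10, 1, 10, correct_extremes = FALSE), "extreme")
})

test_that("per-pair d-prime pools false alarms over the same pairs per block", {
  sched <- build_discrimination_schedule(discrimination_design(), seed = 4)
  m <- behavioral_gen_model()
  trials <- simulate_discrimination_responses(m, sched, "pre", seed = 5)
  dd <- dprime_by_pair(trials)
  expect_equal(nrow(dd), 4 * 3)  # 4 blocks x 3 different-pair types
  expect_equal(unique(dd$n_different), 10)  # 2 screen orders x 5 per block
  expect_equal(unique(dd$n_same), 20)
  # manual check for one cell
  b2 <- trials[trials$block == 2, ]
  manual <- dprime(
    sum(b2$pair_type == "between_35" & b2$response == "different"), 10,
    sum(b2$is_same & b2$response == "different"), 20
  )$dprime
  expect_equal(dd$dprime[dd$block == 2 & dd$pair_type == "between_35"], manual)
})

test_that("the CP contrast is the between minus mean-within difference", {
  dp <- tibble::tibble(
    pair_type = c("within_13", "within_57", "between_35"),
    dprime = c(1.0, 1.0, 1.5)
  )
  expect_equal(cp_contrast(dp), 0.5)
  dp$dprime <- c(2, 2, 2)
  expect_equal(cp_contrast(dp), 0)
  # invariant under adding a constant to all three
  dp$dprime <- c(0.7, 1.1, 1.6)
  expect_equal(cp_contrast(dplyr::mutate(dp, dprime = dprime + 3)),
               cp_contrast(dp))
  expect_error(cp_contrast(dp[-3, ]), "between_35")
})

test_that("training bins aggregate 15 trials and 15 responses as designed", {
  dim_cr <- dimension_spec("CR")
  sched <- build_training_schedule(training_design(), dim_cr, seed = 6)
  m <- behavioral_gen_model()
  trials <- simulate_training_responses(m, sched, seed = 7)
  binned <- bin_training(trials, training_design(), dim_cr)
  expect_equal(nrow(binned$trial_bins), 30)  # 3 blocks x 10 bins
  expect_true(all(binned$trial_bins$n == 15))
  b1 <- binned$stimulus_bins[binned$stimulus_bins$block == 1, ]
  expect_equal(nrow(b1), 10)
  expect_true(all(b1$n == 15))  # uniform block: exactly 15 responses per bin
  # all-correct and alternating tables give the trivial accuracies
  t2 <- trials
  t2$correct <- TRUE
  expect_true(all(bin_training(t2, training_design(), dim_cr)$trial_bins$accuracy == 1))
  t3 <- trials
  t3$correct <- rep(c(TRUE, FALSE), length.out = nrow(t3))
  # 15 trials per bin is odd, so alternation gives 7/15 or 8/15
  expect_lt(max(abs(bin_training(t3, training_design(),
                                 dim_cr)$trial_bins$accuracy - 0.5)), 0.04)
  bad <- trials[-1, ]
  expect_error(bin_training(bad, training_design(), dim_cr), "whole trial bins")
})

test_that("psychometric ML fit matches a grid-search oracle and self-recovers", {
  x <- seq(-90, 90, by = 20)
  # noiseless data exactly on the curve
  p <- 1 / (1 + exp(-0.08 * (x - 5)))
  bins <- tibble::tibble(bin_center = x, n = 1000, n_b = round(1000 * p))
  fit <- fit_psychometric(bins, n_boot = 0)
  expect_true(fit$converged)
  expect_equal(fit$threshold, 5, tolerance = 0.1)
  expect_equal(fit$slope, 0.08, tolerance = 0.005)
  expect_equal(fit$beta_scale, 1 / fit$slope)

  # noisy draw: ML estimate equals a fine 2-D grid search of the likelihood
  set.seed(8)
  bins2 <- tibble::tibble(bin_center = x, n = 15,
                          n_b = rbinom(length(x), 15, p))
  fit2 <- fit_psychometric(bins2, n_boot = 0)
  grid_a <- seq(-30, 30, by = 0.25)
  grid_b <- seq(0.02, 0.2, by = 0.001)
  ll <- outer(grid_a, grid_b, Vectorize(function(a, b) {
    pp <- pmin(pmax(1 / (1 + exp(-b * (x - a))), 1e-12), 1 - 1e-12)
    sum(dbinom(bins2$n_b, bins2$n, pp, log = TRUE))
  }))
  best <- arrayInd(which.max(ll), dim(ll))
  expect_lt(abs(fit2$threshold - grid_a[best[1]]), 0.3)
  expect_lt(abs(fit2$slope - grid_b[best[2]]), 0.002)

  # degenerate data yield a non-converged result, no exception
  dg <- tibble::tibble(bin_center = x, n = 15, n_b = rep(0, length(x)))
  expect_false(fit_psychometric(dg)$converged)
  expect_error(fit_psychometric(bins[1:3, ]), "at least 4 bins")
})

test_that("bootstrap CIs cover the generative slope at roughly nominal rate", {
  dim_cr <- dimension_spec("CR")
  sched <- build_training_schedule(training_design(), dim_cr, seed = 10)
  m <- behavioral_gen_model()
  cover <- vapply(1:40, function(s) {
    trials <- simulate_training_responses(m, sched, seed = 200 + s)
    sb <- bin_training(trials, training_design(), dim_cr)$stimulus_bins
    fit <- fit_psychometric(sb[sb$block == 1, ], n_boot = 120, seed = s)
    gen <- trials$gen_slope[trials$block == 1][1]
    fit$converged && fit$slope_lo <= gen && gen <= fit$slope_hi
  }, logical(1))
  expect_gt(mean(cover), 0.85)  # ~95% nominal, wide binomial band at n = 40
})

test_that("fitted slopes steepen across blocks for simulated learners", {
  dim_cr <- dimension_spec("CR")
  des <- training_design()
  m <- behavioral_gen_model()  # slope means 0.06 / 0.10 / 0.14
  increases <- vapply(1:25, function(s) {
    sched <- build_training_schedule(des, dim_cr, seed = 300 + s)
    trials <- simulate_training_responses(m, sched, seed = 400 + s)
    sb <- bin_training(trials, des, dim_cr)$stimulus_bins
    fits <- vapply(1:3, function(b) {
      fit_psychometric(sb[sb$block == b, ], n_boot = 0)$slope
    }, numeric(1))
    all(diff(fits) > 0)
  }, logical(1))
  expect_gt(mean(increases), 0.6)  # per-block SDs allow occasional inversions
})

test_that("variance-ratio test matches manual arithmetic and scales", {
  set.seed(12)
  a <- rnorm(38)
  b <- rnorm(38)
  vt <- variance_ratio_test(a, b)
  expect_equal(vt$f, var(a) / var(b), tolerance = 1e-12)
  expect_equal(c(vt$df1, vt$df2), c(37, 37))
  manual_p <- 2 * min(pf(vt$f, 37, 37), pf(vt$f, 37, 37, lower.tail = FALSE))
  expect_equal(vt$p, manual_p, tolerance = 1e-12)
  expect_equal(variance_ratio_test(a, a)$f, 1)
  expect_equal(variance_ratio_test(2 * a, a)$f, 4, tolerance = 1e-12)
  expect_error(variance_ratio_test(a, rep(1, 5)), "zero variance")
})

test_that("trait correlations behave at the edges and recover rho", {
  x <- 1:20
  expect_equal(correlate_with_traits(x, x)$r, 1)
  set.seed(13)
  y <- -2 * x + rnorm(20, sd = 1e-6)
  expect_equal(correlate_with_traits(x, y)$r, -1, tolerance = 1e-6)
  expect_error(correlate_with_traits(x, rep(1, 20)), "constant input")
  # Monte Carlo at rho = -0.3, n = 76
  rho <- -0.3
  rs <- vapply(1:300, function(s) {
    withr::with_seed(500 + s, {
      u <- rnorm(76)
      v <- rho * u + sqrt(1 - rho^2) * rnorm(76)
      correlate_with_traits(u, v)$r
    })
  }, numeric(1))
  expect_equal(mean(rs), rho, tolerance = 0.03)
})
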