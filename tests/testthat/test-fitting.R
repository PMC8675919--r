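# a quantile_summary built by hand with full control over its fields
make_summary <- function(condition = "A:0", trial_type = "target_on",
                         n_correct, n_error, correct_q, error_q,
                         obs_correct, obs_error, mean_rt = 0.5,
                         min_rt = 0.3) {
  grid <- condition_grid()
  row <- grid[grid$condition == condition, ]
  structure(
    list(condition = condition, target = row$target,
         trial_type = trial_type, n_background = row$n_background,
         n_correct = n_correct, n_error = n_error,
         correct_q = correct_q, error_q = error_q,
         obs_correct = obs_correct, obs_error = obs_error,
         mean_rt = mean_rt, min_rt = min_rt,
         probs = c(0.1, 0.3, 0.5, 0.7, 0.9)),
    class = "quantile_summary"
  )
}

test_that("quantile binning yields the implied fractions and conserves counts", {
  rt <- seq(0.3, 1.3, length.out = 100)
  tr <- manual_trials("s1", 1, correct = rep(TRUE, 100), rt = rt)
  tr$rt_normalized <- tr$rt_raw
  qs <- quantile_summary(tr)
  expect_equal(qs$obs_correct, c(10, 20, 20, 20, 20, 10))
  expect_equal(length(qs$obs_correct) + length(qs$obs_error), 6)
  expect_equal(sum(qs$obs_correct), qs$n_correct)
  expect_true(all(diff(qs$correct_q) >= 0))
  # duplicated RTs straddling quantiles still conserve the count
  rt2 <- rep(c(0.4, 0.5, 0.5, 0.5, 0.9), 10)
  tr2 <- manual_trials("s1", 1, correct = rep(TRUE, 50), rt = rt2)
  tr2$rt_normalized <- tr2$rt_raw
  qs2 <- quantile_summary(tr2)
  expect_equal(sum(qs2$obs_correct), 50)
  # both response types present: 12 statistics
  tr3 <- manual_trials("s1", 1,
                       correct = c(rep(TRUE, 60), rep(FALSE, 40)),
                       rt = runif(100, 0.3, 1.3))
  tr3$rt_normalized <- tr3$rt_raw
  qs3 <- quantile_summary(tr3)
  expect_equal(length(qs3$obs_correct) + length(qs3$obs_error), 12)
  # sparse response type collapses to two median bins
  tr4 <- manual_trials("s1", 1,
                       correct = c(rep(TRUE, 90), rep(FALSE, 8)),
                       rt = runif(98, 0.3, 1.3))
  tr4$rt_normalized <- tr4$rt_raw
  qs4 <- quantile_summary(tr4)
  expect_equal(length(qs4$obs_error), 2)
  expect_equal(sum(qs4$obs_error), 8)
  expect_error(quantile_summary(rbind(tr3, manual_trials(
    "s1", 1, correct = TRUE, rt = 0.5, condition = "A:1",
    n_background = 1))), "one condition")
})

test_that("expected frequencies reproduce matching observations exactly", {
  # no contamination: if the summary's quantiles are the theoretical
  # conditional quantiles, expected counts equal observed counts
  pars <- ddm_params(drift = 1.2, diffusion_var = 1, threshold = 0.6,
                     start_bias = 0.1, non_decision_time = 0.2)
  probs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  pu <- choice_probability(pars)
  n_tot <- 1000
  qU <- fpt_quantile(pars, probs, "upper") + 0.2
  qL <- fpt_quantile(pars, probs, "lower") + 0.2
  fr <- c(0.1, 0.2, 0.2, 0.2, 0.2, 0.1)
  s <- make_summary(n_correct = n_tot * pu, n_error = n_tot * (1 - pu),
                    correct_q = qU, error_q = qL,
                    obs_correct = n_tot * pu * fr,
                    obs_error = n_tot * (1 - pu) * fr)
  ef <- expected_frequencies(pars, s, outlier_rate = 0)
  expect_equal(ef$correct, s$obs_correct, tolerance = 1e-6)
  expect_equal(ef$error, s$obs_error, tolerance = 1e-6)
  # joint total is the condition's trial count under defective normalization
  expect_equal(sum(ef$correct) + sum(ef$error), n_tot, tolerance = 1e-6)
  # within-type normalization: each type sums to its own count
  ef2 <- expected_frequencies(pars, s, outlier_rate = 0.05,
                              normalization = "within")
  expect_equal(sum(ef2$correct), n_tot * pu, tolerance = 1e-6)
  expect_equal(sum(ef2$error), n_tot * (1 - pu), tolerance = 1e-6)
})

test_that("expected bin fractions match large simulations at the generating parameters", {
  set.seed(51)
  gt <- default_ground_truth()
  row <- gt[gt$condition == "A:2", ]
  d <- sim_condition_trials(row, 2e4)
  qs <- quantile_summary(d)
  pars <- ddm_params(row$drift, row$diffusion_var, row$threshold,
                     row$start_bias, row$non_decision_time)
  ef <- expected_frequencies(pars, qs, outlier_rate = 0)
  obs <- c(qs$obs_correct, qs$obs_error)
  ex <- c(ef$correct, ef$error)
  n <- sum(obs)
  se <- sqrt(n * (ex / n) * (1 - ex / n))
  expect_true(all(abs(obs - ex) < 3 * se))
})

test_that("the chi-square objective is zero at self-consistency and minimal near truth", {
  pars <- ddm_params(drift = 1.2, diffusion_var = 1, threshold = 0.6,
                     start_bias = 0, non_decision_time = 0.2)
  probs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  pu <- choice_probability(pars)
  qU <- fpt_quantile(pars, probs, "upper") + 0.2
  qL <- fpt_quantile(pars, probs, "lower") + 0.2
  fr <- c(0.1, 0.2, 0.2, 0.2, 0.2, 0.1)
  s <- make_summary(n_correct = 1000 * pu, n_error = 1000 * (1 - pu),
                    correct_q = qU, error_q = qL,
                    obs_correct = 1000 * pu * fr,
                    obs_error = 1000 * (1 - pu) * fr)
  # fitting coordinates: unit diffusion, boundaries (0, 2*theta), m' = (m+1)/2
  par_true <- c(2 * 0.6, 1.2, 0.5, 0.2)
  val <- chi_square_objective(par_true, list(`A:0` = s), outlier_rate = 0)
  expect_lt(val, 1e-10)
  expect_gte(chi_square_objective(par_true + c(0, 0.3, 0, 0),
                                  list(`A:0` = s), outlier_rate = 0), val)
  # objective is nonnegative and penalizes out-of-bounds vectors
  expect_gte(chi_square_objective(c(1, 1, 0.5, 0.2), list(`A:0` = s)), 0)
  expect_gte(chi_square_objective(c(-1, 1, 0.5, 0.2), list(`A:0` = s)), 1e10)
  # drift perturbations in either direction increase the objective
  for (dA in c(-0.4, -0.1, 0.1, 0.4)) {
    expect_gt(chi_square_objective(par_true + c(0, dA, 0, 0),
                                   list(`A:0` = s), outlier_rate = 0), val)
  }
})

test_that("rescaling identities are exact and invertible", {
  raw <- structure(
    list(mouse_id = "m1",
         conditions = data.frame(condition_grid()[1:3, ],
                                 threshold_fit = c(2, 1, 0.5),
                                 drift_fit = c(1, -0.4, 0.3)),
         start_fraction = 0.5, non_decision = 0.21, objective = 10,
         n_evaluations = 100L, converged = TRUE),
    class = "ddm_fit_raw")
  fit <- rescale_parameters(raw)
  expect_equal(fit$conditions$drift, c(0.5, -0.4, 0.6))
  expect_equal(fit$conditions$diffusion_var, c(0.25, 1, 4))
  expect_equal(fit$start_bias, 0)
  expect_equal(fit$threshold, 0.5)
  back <- unscale_parameters(fit)
  expect_equal(back$conditions$threshold_fit, raw$conditions$threshold_fit,
               tolerance = 1e-12)
  expect_equal(back$conditions$drift_fit, raw$conditions$drift_fit,
               tolerance = 1e-12)
  expect_equal(back$start_fraction, raw$start_fraction, tolerance = 1e-12)
  # the two parameterizations describe the same choice process
  for (i in 1:3) {
    tf <- raw$conditions$threshold_fit[i]
    af <- raw$conditions$drift_fit[i]
    p_fitcoord <- choice_probability(
      ddm_params(af, 1, tf / 2, 2 * raw$start_fraction - 1))
    p_rescaled <- choice_probability(
      ddm_params(fit$conditions$drift[i], fit$conditions$diffusion_var[i],
                 0.5, fit$start_bias))
    expect_equal(p_fitcoord, p_rescaled, tolerance = 1e-10)
  }
})

test_that("a quick fit recovers drift signs and produces a complete result", {
  set.seed(52)
  gt <- default_ground_truth()
  d <- balanced_dataset(gt, 150)
  res <- fit_mouse(d, n_restarts = 0, outer_maxit = 40, inner_maxit = 80,
                   seed = 3)
  expect_s3_class(res$raw, "ddm_fit_raw")
  expect_s3_class(res$fit, "ddm_fit")
  expect_equal(length(encode_parameters(res$raw)), 38)
  expect_equal(nrow(res$fit$conditions), 18)
  expect_gte(res$raw$objective, 0)
  on <- res$fit$conditions$trial_type == "target_on"
  expect_true(all(res$fit$conditions$drift[on] > 0))
  expect_true(all(res$fit$conditions$drift[!on] < 0))
  expect_true(all(res$fit$conditions$diffusion_var > 0))
  # missing conditions are a hard error
  expect_error(fit_mouse(d[d$condition != "A:3", ]), "missing")
})
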