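#' Posterior-predictive check of a fitted model
#'
#' For every condition present in the data, simulates responses from the
#' fitted parameters (1000 per condition by default) and tabulates observed
#' against predicted report-present fractions and median reaction times with
#' their (unscaled) median absolute deviations.
#'
#' @param fit A `ddm_fit` object.
#' @param trials The observed (preprocessed) trial table the fit was
#'   obtained from.
#' @param n_sim Simulated responses per condition.
#' @param step Euler step for the simulator, seconds.
#' @return Data frame with one row per condition: observed and predicted
#'   `p`, median RT and MAD, and the trial counts. Deterministic under
#'   `set.seed()`.
#' @export
posterior_predictive_check <- function(fit, trials, n_sim = 1000,
                                       step = 1e-4) {
  if (!inherits(fit, "ddm_fit")) {
    stop("'fit' must be a 'ddm_fit' object", call. = FALSE)
  }
  conds <- intersect(condition_grid()$condition, unique(trials$condition))
  missing <- setdiff(conds, fit$conditions$condition)
  if (length(missing)) {
    stop("fit does not cover conditions: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rt_col <- if (all(is.na(trials$rt_normalized))) "rt_raw" else
    "rt_normalized"
  out <- lapply(conds, function(cc) {
    d <- trials[trials$condition == cc, ]
    pars <- fit_condition_params(fit, cc)
    sim <- simulate_first_passage(pars, n_sim, step)
    sim_rt <- sim$decision_time + fit$non_decision
    obs_rt <- d[[rt_col]]
    data.frame(
      condition = cc, target = d$target_identity[1],
      trial_type = d$trial_type[1], n_background = d$n_background[1],
      n_obs = nrow(d),
      observed_p = mean(d$choice == "report_present"),
      predicted_p = mean(sim$boundary == "upper"),
      observed_median_rt = median(obs_rt),
      observed_mad_rt = median(abs(obs_rt - median(obs_rt))),
      predicted_median_rt = median(sim_rt),
      predicted_mad_rt = median(abs(sim_rt - median(sim_rt))),
      n_simulated = n_sim, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Across-mouse drift and diffusion trends
#'
#' Summarizes fitted drift and diffusion variance as a function of the
#' number of background odorants, by trial type, across mice. Within each
#' mouse the two target identities are pooled by simple averaging before the
#' across-mouse mean and standard error are taken.
#'
#' @param fits List of `ddm_fit` objects (one per mouse).
#' @return Data frame: `trial_type`, `n_background`, `mean_drift`,
#'   `se_drift`, `mean_diffusion`, `se_diffusion`, `n_mice`. Standard
#'   errors are `NA` with a single mouse.
#' @export
parameter_trends <- function(fits) {
  if (inherits(fits, "ddm_fit")) fits <- list(fits)
  per_mouse <- lapply(fits, function(f) {
    cond <- f$conditions
    agg <- aggregate(cbind(drift, diffusion_var) ~ trial_type + n_background,
                     data = cond, FUN = mean)
    agg$mouse_id <- f$mouse_id
    agg
  })
  all <- do.call(rbind, per_mouse)
  cells <- unique(all[, c("trial_type", "n_background")])
  cells <- cells[order(cells$trial_type, cells$n_background), ]
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  out <- lapply(seq_len(nrow(cells)), function(i) {
    d <- all[all$trial_type == cells$trial_type[i] &
               all$n_background == cells$n_background[i], ]
    data.frame(trial_type = cells$trial_type[i],
               n_background = cells$n_background[i],
               mean_drift = mean(d$drift), se_drift = se(d$drift),
               mean_diffusion = mean(d$diffusion_var),
               se_diffusion = se(d$diffusion_var),
               n_mice = nrow(d), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# least-squares slope of y on x
.slope <- function(x, y) {
  if (length(unique(x)) < 2) return(NA_real_)
  unname(coef(lm(y ~ x))[2])
}

#' Parameter-recovery report
#'
#' Compares fitted per-condition parameters against the generating ground
#' truth: bias, root-mean-square error and truth-estimate correlation for
#' the drift and diffusion-variance classes, plus agreement of the
#' background trends (the sign of the slope of drift magnitude and of
#' diffusion variance against background count, per trial type).
#'
#' @param ground_truth Ground-truth table (see [default_ground_truth()]).
#' @param fit A `ddm_fit` obtained from data generated under
#'   `ground_truth`.
#' @return List with `metrics` (per parameter class) and `trends` (per
#'   trial type and class: truth and estimate slopes and whether their
#'   signs agree).
#' @export
parameter_recovery_report <- function(ground_truth, fit) {
  if (!inherits(fit, "ddm_fit")) {
    stop("'fit' must be a 'ddm_fit' object", call. = FALSE)
  }
  idx <- match(fit$conditions$condition, ground_truth$condition)
  if (any(is.na(idx))) {
    stop("ground truth and fit cover different condition sets",
         call. = FALSE)
  }
  truth <- ground_truth[idx, ]
  est <- fit$conditions
  # express the truth in the fit's threshold convention (theta = 1/2):
  # (theta, A, c^2) -> (lambda theta, lambda A, lambda^2 c^2) leaves the
  # process invariant, so rescale the truth by lambda = 0.5 / theta_truth
  lambda <- 0.5 / truth$threshold
  truth_drift <- truth$drift * lambda
  truth_diff <- truth$diffusion_var * lambda^2
  one_class <- function(tr, es, class) {
    data.frame(class = class, bias = mean(es - tr),
               rmse = sqrt(mean((es - tr)^2)),
               correlation = if (sd(tr) > 0 && sd(es) > 0) cor(tr, es)
                 else NA_real_,
               stringsAsFactors = FALSE)
  }
  metrics <- rbind(one_class(truth_drift, est$drift, "drift"),
                   one_class(truth_diff, est$diffusion_var, "diffusion_var"))
  trends <- do.call(rbind, lapply(c("target_on", "target_off"), function(tt) {
    sel <- est$trial_type == tt
    n <- est$n_background[sel]
    rbind(
      data.frame(trial_type = tt, class = "abs_drift",
                 truth_slope = .slope(n, abs(truth_drift[sel])),
                 estimate_slope = .slope(n, abs(est$drift[sel]))),
      data.frame(trial_type = tt, class = "diffusion_var",
                 truth_slope = .slope(n, truth_diff[sel]),
                 estimate_slope = .slope(n, est$diffusion_var[sel]))
    )
  }))
  trends$sign_agrees <- sign(trends$truth_slope) == sign(trends$estimate_slope)
  rownames(trends) <- NULL
  list(metrics = metrics, trends = trends)
}
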