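#' The 18-condition design grid
#'
#' Conditions are defined by the target mode (target A on, target B on, no
#' target) crossed with the number of background odorants. A target-on
#' mixture of `x` components carries `x - 1` backgrounds (0-5); a target-off
#' mixture of `x` components carries `x` backgrounds (1-6).
#'
#' @return Data frame with columns `condition` (key string), `target`
#'   (`"A"`, `"B"`, `"none"`), `trial_type` and `n_background`; 18 rows.
#' @export
condition_grid <- function() {
  on <- expand.grid(target = c("A", "B"), n_background = 0:5,
                    stringsAsFactors = FALSE)
  on$trial_type <- "target_on"
  off <- data.frame(target = "none", n_background = 1:6,
                    trial_type = "target_off", stringsAsFactors = FALSE)
  grid <- rbind(on[, c("target", "trial_type", "n_background")], off)
  grid <- grid[order(grid$target, grid$n_background), ]
  grid <- data.frame(condition = paste0(grid$target, ":", grid$n_background),
                     grid, stringsAsFactors = FALSE)
  rownames(grid) <- NULL
  grid
}

#' Mixture-complexity distribution
#'
#' Probability that a trial's mixture has `x` components (`x = 1..6`),
#' proportional to `b^x`. `b = 1` gives a uniform distribution; smaller `b`
#' favours simple (easy) mixtures and is how session difficulty is
#' controlled.
#'
#' @param b Complexity parameter in (0, 1].
#' @return Probability vector of length 6 over `x = 1..6` (sums to 1).
#' @examples
#' complexity_pmf(1)    # uniform
#' complexity_pmf(0.5)  # p(1) = 32/63
#' @export
complexity_pmf <- function(b) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0 || b > 1) {
    stop("'b' must be a single number in (0, 1]", call. = FALSE)
  }
  w <- b^(1:6)
  w / sum(w)
}

#' Adaptive target-on probability
#'
#' The probability that the next trial is target-on equals one minus the
#' fraction of "report present" choices (licks to the target-present side)
#' among the last five responded trials. This negative feedback counteracts
#' side biases: an animal that keeps reporting "present" receives more
#' target-off trials. With no history yet, the probability is 1/2.
#'
#' @param recent_choices Character vector (most recent trials' choices,
#'   values `"report_present"`/`"report_absent"`) of length <= 5, or a
#'   logical vector (`TRUE` = report present). Length 0 allowed.
#' @return Probability in `[0, 1]` that the next trial is target-on.
#' @export
next_target_probability <- function(recent_choices) {
  if (length(recent_choices) == 0) return(0.5)
  if (length(recent_choices) > 5) {
    stop("'recent_choices' must contain at most the last 5 trials",
         call. = FALSE)
  }
  present <- if (is.logical(recent_choices)) recent_choices else
    recent_choices == "report_present"
  1 - mean(present)
}

#' Per-condition ground-truth parameter tables
#'
#' Builds the map from the 18 task conditions to generating DDM parameters
#' used by the synthetic-data generator. All variants share the threshold
#' convention of the fitting stage (`theta = 1/2`), a mild bias toward
#' reporting "present" and a common non-decision time; they differ in how
#' drift and diffusion depend on the background count `n`:
#'
#' * `"combined"` (default; emulates the regime the fits point to): drift
#'   magnitude shrinks and diffusion variance grows with `n`
#'   (`A_on = a_on - k_drift * n`, `A_off = a_off + k_drift * n`,
#'   `c2 = c2_0 + k_diff * n`).
#' * `"noise_boost"`: drifts flat, diffusion grows.
#' * `"signal_reduction"`: drift magnitude shrinks, diffusion flat.
#' * `"false_signal"`: both drifts *increase* with `n`, diffusion flat.
#' * `"flat"`: no background dependence at all (negative control).
#'
#' The target-A and target-B rows share the target-on parameters.
#'
#' @param mechanism Variant name, see above.
#' @param a_on,a_off Baseline drifts at zero backgrounds (on > 0 > off).
#' @param c2_0 Baseline diffusion variance.
#' @param k_drift,k_diff Per-background increments for drift magnitude and
#'   diffusion variance.
#' @param start_bias,non_decision_time,threshold Shared across conditions.
#' @return Data frame: [condition_grid()] columns plus `drift`,
#'   `diffusion_var`, `threshold`, `start_bias`, `non_decision_time`.
#' @export
default_ground_truth <- function(mechanism = c("combined", "noise_boost",
                                               "signal_reduction",
                                               "false_signal", "flat"),
                                 a_on = 1.6, a_off = -1.9, c2_0 = 0.6,
                                 k_drift = 0.2, k_diff = 0.12,
                                 start_bias = 0.1, non_decision_time = 0.25,
                                 threshold = 0.5) {
  mechanism <- match.arg(mechanism)
  grid <- condition_grid()
  n <- grid$n_background
  on <- grid$trial_type == "target_on"
  drift <- diffusion <- numeric(nrow(grid))
  kd <- switch(mechanism, combined = , signal_reduction = k_drift,
               false_signal = -k_drift, 0)
  kc <- switch(mechanism, combined = , noise_boost = k_diff, 0)
  drift[on] <- a_on - kd * n[on]
  drift[!on] <- a_off + kd * n[!on]
  diffusion <- c2_0 + kc * n
  out <- cbind(grid,
               data.frame(drift = drift, diffusion_var = diffusion,
                          threshold = threshold, start_bias = start_bias,
                          non_decision_time = non_decision_time))
  rownames(out) <- NULL
  out
}

# look up one condition's ddm_params in a ground-truth table
.gt_params <- function(ground_truth, condition) {
  row <- ground_truth[ground_truth$condition == condition, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("ground truth is missing condition '", condition, "'",
         call. = FALSE)
  }
  ddm_params(drift = row$drift, diffusion_var = row$diffusion_var,
             threshold = row$threshold, start_bias = row$start_bias,
             non_decision_time = row$non_decision_time)
}

#' Configuration of the synthetic behavioural task
#'
#' Collects everything the generator needs to emulate one mouse's dataset:
#' the per-condition generating parameters, session structure (number of
#' sessions, trials per session drawn around 250 +/- 20), the complexity
#' levels from which each session's `b` is sampled, the 5-trial adaptive
#' window, the 2.8 s response window, the 200 ms odor line delay (already
#' subtracted from generated reaction times, which are therefore on the
#' delay-corrected clock), and the contamination rate.
#'
#' @param ground_truth Per-condition parameter table, see
#'   [default_ground_truth()]. Must cover all 18 conditions and use a single
#'   shared non-decision time.
#' @param n_sessions Number of analyzable sessions.
#' @param trials_per_session_mean,trials_per_session_sd Normal distribution
#'   (rounded, floored at 50) of trials per session.
#' @param complexity_levels Values from which each session's `b` is drawn
#'   uniformly; data-collection sessions use `b >= 0.5`.
#' @param n_training_sessions Extra low-complexity sessions (b in
#'   {0.1, 0.25}) prepended to exercise the training-session filter; 0 by
#'   default.
#' @param adaptive_window Number of recent responded trials feeding
#'   [next_target_probability()].
#' @param response_window,odor_delay Seconds.
#' @param outlier_rate Contaminant probability per trial.
#' @param step Euler step for the trial simulator, seconds.
#' @param mouse_id Identifier stamped on every trial.
#' @return Object of class `task_config`.
#' @export
task_config <- function(ground_truth = default_ground_truth(),
                        n_sessions = 70,
                        trials_per_session_mean = 250,
                        trials_per_session_sd = 20,
                        complexity_levels = c(0.5, 0.75, 1),
                        n_training_sessions = 0,
                        adaptive_window = 5,
                        response_window = 2.8,
                        odor_delay = 0.2,
                        outlier_rate = 0.02,
                        step = 1e-4,
                        mouse_id = "m1") {
  grid <- condition_grid()
  missing <- setdiff(grid$condition, ground_truth$condition)
  if (length(missing)) {
    stop("ground truth must cover all 18 conditions; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(unique(ground_truth$non_decision_time)) != 1L) {
    stop("ground truth must share one non-decision time", call. = FALSE)
  }
  if (outlier_rate < 0 || outlier_rate >= 1) {
    stop("'outlier_rate' must lie in [0, 1)", call. = FALSE)
  }
  if (any(complexity_levels <= 0 | complexity_levels > 1)) {
    stop("'complexity_levels' must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(ground_truth = ground_truth, n_sessions = n_sessions,
         trials_per_session_mean = trials_per_session_mean,
         trials_per_session_sd = trials_per_session_sd,
         complexity_levels = complexity_levels,
         n_training_sessions = n_training_sessions,
         adaptive_window = adaptive_window,
         response_window = response_window, odor_delay = odor_delay,
         outlier_rate = outlier_rate, step = step, mouse_id = mouse_id),
    class = "task_config"
  )
}

#' Generate one synthetic mouse's behavioural dataset
#'
#' Emulates the experiment trial by trial. Within each session, the trial
#' type is drawn with the adaptive probability computed from the simulated
#' animal's own last five responded choices; the mixture size is drawn from
#' the session's complexity distribution; the trial's choice and reaction
#' time come from the DDM at the condition's ground-truth parameters (or
#' from the uniform contaminant process). Trials whose reaction time falls
#' outside the response window are omitted and counted, and do not enter the
#' choice history.
#'
#' @param config A [task_config()].
#' @return Data frame with one row per responded trial: `mouse_id`,
#'   `session_id`, `session_b`, `condition`, `target_identity`,
#'   `trial_type`, `n_background`, `choice`, `correct`, `rt_raw`
#'   (delay-corrected seconds), `rt_normalized` (`NA` until
#'   [normalize_reaction_times()]). Attribute `n_omitted` counts omitted
#'   trials. Deterministic under `set.seed()`.
#' @examples
#' set.seed(7)
#' cfg <- task_config(n_sessions = 2, trials_per_session_mean = 60)
#' d <- generate_mouse_dataset(cfg)
#' table(d$trial_type)
#' @export
generate_mouse_dataset <- function(config) {
  if (!inherits(config, "task_config")) {
    stop("'config' must be a 'task_config' object", call. = FALSE)
  }
  gt <- config$ground_truth
  ter <- gt$non_decision_time[1]
  window <- config$response_window
  grid <- condition_grid()

  session_bs <- c(
    sample(c(0.1, 0.25), config$n_training_sessions, replace = TRUE),
    sample(config$complexity_levels, config$n_sessions, replace = TRUE)
  )
  n_total_sessions <- length(session_bs)

  # parameter lookup vectors for speed
  key <- gt$condition
  rows <- list()
  n_omitted <- 0L
  for (s in seq_len(n_total_sessions)) {
    b <- session_bs[s]
    pmf <- complexity_pmf(b)
    n_trials <- max(50L, as.integer(round(rnorm(1, config$trials_per_session_mean,
                                                config$trials_per_session_sd))))
    choice_hist <- character(0)
    mouse <- character(n_trials); sess <- character(n_trials)
    cond <- character(n_trials); targ <- character(n_trials)
    ttype <- character(n_trials); nbg <- integer(n_trials)
    choice <- character(n_trials); rt <- numeric(n_trials)
    kept <- logical(n_trials)
    for (i in seq_len(n_trials)) {
      p_on <- next_target_probability(choice_hist)
      on <- runif(1) < p_on
      x <- sample.int(6L, 1L, prob = pmf)
      if (on) {
        target <- if (runif(1) < 0.5) "A" else "B"
        n_background <- x - 1L
      } else {
        target <- "none"
        n_background <- x
      }
      cond_key <- paste0(target, ":", n_background)
      idx <- match(cond_key, key)
      if (runif(1) < config$outlier_rate) {
        this_rt <- runif(1, ter, window)
        this_up <- runif(1) < 0.5
      } else {
        sim <- cpp_sim_fp(1L, gt$drift[idx], gt$diffusion_var[idx],
                          gt$threshold[idx], gt$start_bias[idx],
                          config$step, TRUE, 1e7)
        this_rt <- sim$decision_time[1] + ter
        this_up <- !is.na(sim$upper[1]) && sim$upper[1] == 1L
      }
      if (is.na(this_rt) || this_rt > window) {
        n_omitted <- n_omitted + 1L
        next
      }
      this_choice <- if (this_up) "report_present" else "report_absent"
      choice_hist <- c(choice_hist, this_choice)
      if (length(choice_hist) > config$adaptive_window) {
        choice_hist <- choice_hist[length(choice_hist) -
                                     config$adaptive_window + seq_len(config$adaptive_window)]
      }
      kept[i] <- TRUE
      mouse[i] <- config$mouse_id
      sess[i] <- sprintf("%s_s%03d", config$mouse_id, s)
      cond[i] <- cond_key
      targ[i] <- target
      ttype[i] <- if (on) "target_on" else "target_off"
      nbg[i] <- n_background
      choice[i] <- this_choice
      rt[i] <- this_rt
    }
    rows[[s]] <- data.frame(
      mouse_id = mouse[kept], session_id = sess[kept], session_b = b,
      condition = cond[kept], target_identity = targ[kept],
      trial_type = ttype[kept], n_background = nbg[kept],
      choice = choice[kept],
      correct = (choice[kept] == "report_present") == (ttype[kept] == "target_on"),
      rt_raw = rt[kept], rt_normalized = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_omitted") <- n_omitted
  out
}

#' Generate a cohort of synthetic mice
#'
#' Applies [generate_mouse_dataset()] to several mice that share one task
#' configuration (mouse ids `m1`, `m2`, ...), concatenating the results.
#'
#' @param n_mice Number of mice.
#' @param config Base [task_config()]; its `mouse_id` is overridden.
#' @return Combined trial table; attribute `n_omitted` sums over mice.
#' @export
generate_cohort <- function(n_mice = 6, config = task_config()) {
  out <- vector("list", n_mice)
  omitted <- 0L
  for (i in seq_len(n_mice)) {
    cfg <- config
    cfg$mouse_id <- paste0("m", i)
    out[[i]] <- generate_mouse_dataset(cfg)
    omitted <- omitted + attr(out[[i]], "n_omitted")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_omitted") <- omitted
  res
}
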