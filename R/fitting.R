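#' Quantile summary of one condition's responses
#'
#' Correct and error responses are summarized separately by the reaction-time
#' quantiles 0.1, 0.3, 0.5, 0.7 and 0.9, which delimit 6 bins per response
#' type whose observed counts carry the fractions (0.1, 0.2, 0.2, 0.2, 0.2,
#' 0.1) of that type's trials: 12 summary statistics per condition. Response
#' types with fewer than 12 trials are collapsed to 2 bins around their
#' median (and a type with no trials contributes no bins); quantiles use
#' linear interpolation of the empirical distribution ([stats::quantile()]
#' type 7).
#'
#' @param trials Trial table rows belonging to a single condition, with
#'   `correct` and reaction times (`rt_normalized` used when filled,
#'   `rt_raw` otherwise).
#' @param probs Quantile levels delimiting the bins.
#' @param qtype Quantile algorithm passed to [stats::quantile()].
#' @return Object of class `quantile_summary`: condition labels, per-type
#'   counts (`n_correct`, `n_error`), quantile reaction times (`correct_q`,
#'   `error_q`) and observed bin counts (`obs_correct`, `obs_error`), plus
#'   the mean reaction time (used to initialize fits).
#' @export
quantile_summary <- function(trials, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                             qtype = 7) {
  if (length(unique(trials$condition)) != 1L) {
    stop("'trials' must contain exactly one condition", call. = FALSE)
  }
  if (nrow(trials) < 1L) stop("need at least one trial", call. = FALSE)
  rt <- if (all(is.na(trials$rt_normalized))) trials$rt_raw else
    trials$rt_normalized
  one_type <- function(x) {
    n <- length(x)
    if (n == 0L) return(list(q = numeric(0), obs = numeric(0)))
    if (n < 12L) {
      q <- unname(quantile(x, 0.5, type = qtype))
    } else {
      q <- unname(quantile(x, probs, type = qtype))
    }
    idx <- findInterval(x, q, left.open = TRUE) + 1L
    list(q = q, obs = as.numeric(tabulate(idx, nbins = length(q) + 1L)))
  }
  co <- one_type(rt[trials$correct])
  er <- one_type(rt[!trials$correct])
  structure(
    list(condition = trials$condition[1],
         target = trials$target_identity[1],
         trial_type = trials$trial_type[1],
         n_background = trials$n_background[1],
         n_correct = sum(trials$correct), n_error = sum(!trials$correct),
         correct_q = co$q, error_q = er$q,
         obs_correct = co$obs, obs_error = er$obs,
         mean_rt = mean(rt), min_rt = min(rt), probs = probs),
    class = "quantile_summary"
  )
}

#' Quantile summaries for all conditions of one mouse
#'
#' @param trials Preprocessed trial table of a single mouse.
#' @return Named list of [quantile_summary()] objects in [condition_grid()]
#'   order (conditions with no trials are dropped).
#' @export
summarize_conditions <- function(trials) {
  grid <- condition_grid()
  present <- intersect(grid$condition, unique(trials$condition))
  out <- lapply(present, function(cc) {
    quantile_summary(trials[trials$condition == cc, , drop = FALSE])
  })
  names(out) <- present
  out
}

# expected bin counts for one response type.
# boundary_upper: does this response type correspond to the upper boundary?
# Mixture of the defective DDM distribution with a uniform contaminant on
# [ter, response_window] that guesses either boundary with probability 1/2.
.expected_type <- function(q, n_type, n_total, boundary_upper, drift, theta,
                           m, ter, outlier_rate, response_window,
                           normalization) {
  r <- 2 * drift * theta  # unit diffusion variance in fitting coordinates
  p_up <- .p_upper(r, m)
  mass_b <- if (boundary_upper) p_up else 1 - p_up
  mass_total <- (1 - outlier_rate) * mass_b + outlier_rate * 0.5
  if (length(q) == 0L) {
    if (normalization == "defective") {
      return(list(obs = 0, exp = n_total * mass_total))
    }
    return(list(obs = numeric(0), exp = numeric(0)))
  }
  td <- pmax(q - ter, 0)
  Fd <- .fpt_cdf_core(td, drift, 1, theta, m, boundary_upper)
  U <- pmin(pmax((q - ter) / (response_window - ter), 0), 1)
  G <- (1 - outlier_rate) * Fd + outlier_rate * 0.5 * U
  if (normalization == "defective") {
    e <- n_total * diff(c(0, G, mass_total))
  } else {
    e <- n_type * diff(c(0, G / mass_total, 1))
  }
  list(obs = NULL, exp = e)
}

#' Expected bin frequencies under the DDM
#'
#' Evaluates the theoretical defective cumulative distribution (mixed with a
#' uniform contaminant component) at a condition's empirical quantile
#' reaction times, differences successive values, and scales to trial
#' counts. Under the default `"defective"` normalization the expected counts
#' of the correct and error bins jointly sum to the condition's total trial
#' count, so both accuracy and reaction-time shape inform the fit; under
#' `"within"` each response type is renormalized to its own count (the
#' expected counts then carry timing information only).
#'
#' @param params [ddm_params()] describing the condition (its
#'   `non_decision_time` is the fitted `Ter`).
#' @param summary A [quantile_summary()].
#' @param outlier_rate Assumed contaminant fraction (the fitting allowance
#'   for discarded responses).
#' @param response_window Support end of the uniform contaminant, seconds.
#' @param normalization `"defective"` or `"within"`, see above.
#' @return List with numeric vectors `correct` and `error` of expected
#'   counts matching the summary's observed bins.
#' @export
expected_frequencies <- function(params, summary, outlier_rate = 0.05,
                                 response_window = 2.8,
                                 normalization = c("defective", "within")) {
  .check_params(params)
  normalization <- match.arg(normalization)
  if (!inherits(summary, "quantile_summary")) {
    stop("'summary' must be a 'quantile_summary' object", call. = FALSE)
  }
  # rescale to unit diffusion (the closed forms depend on the process only
  # through (A, theta, m)/c-scaling, so divide A and theta by c)
  cc <- sqrt(params$diffusion_var)
  drift <- params$drift / cc
  theta <- params$threshold / cc
  m <- params$start_bias
  ter <- params$non_decision_time
  n_total <- summary$n_correct + summary$n_error
  upper_correct <- summary$trial_type == "target_on"
  co <- .expected_type(summary$correct_q, summary$n_correct, n_total,
                       upper_correct, drift, theta, m, ter, outlier_rate,
                       response_window, normalization)
  er <- .expected_type(summary$error_q, summary$n_error, n_total,
                       !upper_correct, drift, theta, m, ter, outlier_rate,
                       response_window, normalization)
  list(correct = co$exp, error = er$exp)
}

# chi-square contribution of one condition in fitting coordinates
# (unit diffusion, threshold theta_fit/2, bias 2 m' - 1)
.cond_chisq <- function(theta_fit, a_fit, m_prime, ter, summary,
                        outlier_rate, response_window, normalization,
                        e_floor) {
  theta <- theta_fit / 2
  m <- 2 * m_prime - 1
  n_total <- summary$n_correct + summary$n_error
  upper_correct <- summary$trial_type == "target_on"
  total <- 0
  for (type in c("correct", "error")) {
    q <- if (type == "correct") summary$correct_q else summary$error_q
    n_type <- if (type == "correct") summary$n_correct else summary$n_error
    obs <- if (type == "correct") summary$obs_correct else summary$obs_error
    up <- if (type == "correct") upper_correct else !upper_correct
    res <- .expected_type(q, n_type, n_total, up, a_fit, theta, m, ter,
                          outlier_rate, response_window, normalization)
    if (length(res$exp) == 0L) next
    if (length(obs) == 0L) obs <- 0
    total <- total + sum((obs - res$exp)^2 / pmax(res$exp, e_floor))
  }
  total
}

.FIT_BOUNDS <- list(theta_fit = c(0.05, 10), drift_fit = c(-20, 20),
                    m_prime = c(0.05, 0.95))

#' Chi-square objective over all conditions
#'
#' The quantity minimized by [fit_mouse()]: the sum over conditions and RT
#' bins of `(O - E)^2 / E` between observed and expected bin frequencies,
#' where `E` is floored at `e_floor` trials. The parameter vector holds, in
#' the order of `summaries`, one threshold (`theta_fit`, unit-diffusion
#' scale) and one drift (`drift_fit`) per condition, followed by the shared
#' start fraction `m_prime` and non-decision time `ter` -- 38 free
#' parameters for the full 18-condition design. Out-of-bounds vectors
#' return a large finite penalty so derivative-free optimizers can recover.
#'
#' @param par Numeric vector `c(theta_fit[1..K], drift_fit[1..K], m_prime,
#'   ter)` for `K = length(summaries)`.
#' @param summaries Named list of [quantile_summary()] objects.
#' @param ter_max Upper bound for `ter` (normally just below the smallest
#'   observed reaction time).
#' @inheritParams expected_frequencies
#' @param e_floor Floor applied to expected counts inside the ratio.
#' @return Nonnegative scalar.
#' @export
chi_square_objective <- function(par, summaries, outlier_rate = 0.05,
                                 response_window = 2.8,
                                 normalization = c("defective", "within"),
                                 e_floor = 1e-3, ter_max = Inf) {
  normalization <- match.arg(normalization)
  k <- length(summaries)
  if (length(par) != 2 * k + 2) {
    stop("'par' must have length ", 2 * k + 2, call. = FALSE)
  }
  theta_fit <- par[seq_len(k)]
  drift_fit <- par[k + seq_len(k)]
  m_prime <- par[2 * k + 1]
  ter <- par[2 * k + 2]
  viol <- sum(pmax(.FIT_BOUNDS$theta_fit[1] - theta_fit, 0) +
                pmax(theta_fit - .FIT_BOUNDS$theta_fit[2], 0)) +
    sum(pmax(.FIT_BOUNDS$drift_fit[1] - drift_fit, 0) +
          pmax(drift_fit - .FIT_BOUNDS$drift_fit[2], 0)) +
    max(.FIT_BOUNDS$m_prime[1] - m_prime, 0) +
    max(m_prime - .FIT_BOUNDS$m_prime[2], 0) +
    max(-ter, 0) + max(ter - ter_max, 0)
  if (viol > 0) return(1e10 * (1 + viol))
  total <- 0
  for (i in seq_len(k)) {
    total <- total + .cond_chisq(theta_fit[i], drift_fit[i], m_prime, ter,
                                 summaries[[i]], outlier_rate,
                                 response_window, normalization, e_floor)
  }
  total
}

# method-of-moments starting values for one condition given (m', ter)
.init_condition <- function(summary, m_prime, ter) {
  n_total <- summary$n_correct + summary$n_error
  upper_n <- if (summary$trial_type == "target_on") summary$n_correct else
    summary$n_error
  p_obs <- min(max(upper_n / n_total, 0.02), 0.98)
  r0 <- qlogis(p_obs)
  e_dt <- max(summary$mean_rt - ter, 0.02)
  th2 <- if (abs(r0) < 1e-6) e_dt else e_dt * r0 / (2 * tanh(r0 / 2))
  theta <- sqrt(max(th2, 1e-4))
  a0 <- if (abs(r0) < 1e-6) 0 else r0 / (2 * theta)
  theta_fit <- min(max(2 * theta, .FIT_BOUNDS$theta_fit[1] * 1.5),
                   .FIT_BOUNDS$theta_fit[2] / 1.5)
  a0 <- min(max(a0, .FIT_BOUNDS$drift_fit[1] / 1.5),
            .FIT_BOUNDS$drift_fit[2] / 1.5)
  c(log(theta_fit), a0)
}

# inner 2-parameter simplex solve for one condition, warm-startable
.solve_condition <- function(summary, m_prime, ter, start, outlier_rate,
                             response_window, normalization, e_floor,
                             maxit, reltol) {
  fn <- function(p) {
    tf <- exp(p[1])
    if (tf < .FIT_BOUNDS$theta_fit[1] || tf > .FIT_BOUNDS$theta_fit[2] ||
        p[2] < .FIT_BOUNDS$drift_fit[1] || p[2] > .FIT_BOUNDS$drift_fit[2]) {
      return(1e10)
    }
    .cond_chisq(tf, p[2], m_prime, ter, summary, outlier_rate,
                response_window, normalization, e_floor)
  }
  opt <- optim(start, fn, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = reltol))
  opt
}

#' Fit the DDM to one mouse by chi-square quantile optimization
#'
#' Minimizes [chi_square_objective()] over one threshold and one drift per
#' condition plus a shared start fraction `m_prime` and non-decision time
#' `ter` (38 parameters for the 18-condition design). The shared parameters
#' are optimized by a Nelder-Mead simplex on a transformed (bounded) scale;
#' at every candidate the per-condition pairs are solved by independent
#' warm-started simplex runs, which is equivalent to the joint minimization
#' because conditions interact only through the shared pair. Additional
#' seeded random restarts of the shared parameters protect against local
#' minima. Deterministic given `seed`.
#'
#' @param trials Preprocessed trial table of a single mouse covering all 18
#'   conditions.
#' @inheritParams expected_frequencies
#' @param n_restarts Extra random outer starts besides the heuristic one.
#' @param seed Integer seed for the restart draws.
#' @param outer_maxit,inner_maxit Simplex iteration caps.
#' @return List with `raw` (class `ddm_fit_raw`: per-condition
#'   `threshold_fit` and `drift_fit`, shared `start_fraction` and
#'   `non_decision`, objective value, evaluation count, convergence flag)
#'   and `fit`, its rescaling by [rescale_parameters()].
#' @export
fit_mouse <- function(trials, outlier_rate = 0.05, response_window = 2.8,
                      normalization = c("defective", "within"),
                      n_restarts = 2, seed = 1, outer_maxit = 120,
                      inner_maxit = 150) {
  normalization <- match.arg(normalization)
  if (length(unique(trials$mouse_id)) > 1L) {
    stop("'trials' must belong to a single mouse", call. = FALSE)
  }
  summaries <- summarize_conditions(trials)
  missing <- setdiff(condition_grid()$condition, names(summaries))
  if (length(missing)) {
    stop("all 18 conditions must be present; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  min_rt <- min(vapply(summaries, `[[`, numeric(1), "min_rt"))
  ter_max <- 0.999 * min_rt
  k <- length(summaries)
  n_eval <- 0L
  memo <- new.env(parent = emptyenv())

  inner_all <- function(m_prime, ter, maxit, reltol) {
    vals <- numeric(k)
    for (i in seq_len(k)) {
      key <- names(summaries)[i]
      start <- if (!is.null(memo[[key]])) memo[[key]] else
        .init_condition(summaries[[i]], m_prime, ter)
      opt <- .solve_condition(summaries[[i]], m_prime, ter, start,
                              outlier_rate, response_window, normalization,
                              1e-3, maxit, reltol)
      n_eval <<- n_eval + opt$counts[1]
      memo[[key]] <- opt$par
      vals[i] <- opt$value
    }
    sum(vals)
  }
  outer_fn <- function(u) {
    m_prime <- 0.05 + 0.9 * plogis(u[1])
    ter <- ter_max * plogis(u[2])
    inner_all(m_prime, ter, inner_maxit, 1e-6)
  }

  if (!is.null(seed)) set.seed(seed)
  starts <- list(c(0, qlogis(0.85)))
  if (n_restarts > 0) {
    for (j in seq_len(n_restarts)) {
      mp <- runif(1, 0.35, 0.65)
      tt <- runif(1, 0.4, 0.95)
      starts[[j + 1L]] <- c(qlogis((mp - 0.05) / 0.9), qlogis(tt))
    }
  }
  best <- NULL
  for (st in starts) {
    rm(list = ls(envir = memo), envir = memo)
    opt <- optim(st, outer_fn, method = "Nelder-Mead",
                 control = list(maxit = outer_maxit, reltol = 1e-6))
    sol <- as.list(memo)
    if (is.null(best) || opt$value < best$value) {
      best <- list(value = opt$value, par = opt$par,
                   convergence = opt$convergence, memo = sol)
    }
  }
  # polish at the best shared parameters
  rm(list = ls(envir = memo), envir = memo)
  for (key in names(best$memo)) memo[[key]] <- best$memo[[key]]
  m_prime <- 0.05 + 0.9 * plogis(best$par[1])
  ter <- ter_max * plogis(best$par[2])
  inner_all(m_prime, ter, 400, 1e-9)

  theta_fit <- vapply(names(summaries), function(kk) exp(memo[[kk]][1]),
                      numeric(1))
  drift_fit <- vapply(names(summaries), function(kk) memo[[kk]][2],
                      numeric(1))
  grid <- condition_grid()
  ord <- match(names(summaries), grid$condition)
  conditions <- data.frame(grid[ord, ],
                           threshold_fit = unname(theta_fit),
                           drift_fit = unname(drift_fit),
                           stringsAsFactors = FALSE)
  rownames(conditions) <- NULL
  par_vec <- c(unname(theta_fit), unname(drift_fit), m_prime, ter)
  objective <- chi_square_objective(par_vec, summaries, outlier_rate,
                                    response_window, normalization,
                                    ter_max = ter_max)
  raw <- structure(
    list(mouse_id = trials$mouse_id[1], conditions = conditions,
         start_fraction = m_prime, non_decision = ter,
         objective = objective, n_evaluations = n_eval,
         converged = best$convergence == 0,
         normalization = normalization, outlier_rate = outlier_rate,
         response_window = response_window),
    class = "ddm_fit_raw"
  )
  list(raw = raw, fit = rescale_parameters(raw))
}

#' Encode a raw fit as the 38-parameter vector
#'
#' @param raw A `ddm_fit_raw` object.
#' @return Numeric vector in the layout [chi_square_objective()] expects.
#' @export
encode_parameters <- function(raw) {
  if (!inherits(raw, "ddm_fit_raw")) {
    stop("'raw' must be a 'ddm_fit_raw' object", call. = FALSE)
  }
  c(raw$conditions$threshold_fit, raw$conditions$drift_fit,
    raw$start_fraction, raw$non_decision)
}

#' Rescale fitted parameters to drift/diffusion units
#'
#' The fitting stage works in unit-diffusion coordinates with boundaries at
#' 0 and `theta_fit` and start fraction `m_prime`. Because the threshold is
#' a scaling parameter of the drift and of the square root of the diffusion
#' variance, fixing the threshold instead (`theta' = 1`, i.e. symmetric
#' boundaries at +-1/2) converts each condition's pair into drift and
#' diffusion-variance units via the exact identities `A = A_fit/theta_fit`,
#' `c^2 = 1/theta_fit^2`, and `m = 2 m_prime - 1`.
#'
#' @param raw A `ddm_fit_raw` object (all `threshold_fit` > 0).
#' @return Object of class `ddm_fit` with per-condition `drift` and
#'   `diffusion_var`, shared `start_bias`, `non_decision` and the fixed
#'   `threshold = 1/2`.
#' @export
rescale_parameters <- function(raw) {
  if (!inherits(raw, "ddm_fit_raw")) {
    stop("'raw' must be a 'ddm_fit_raw' object", call. = FALSE)
  }
  if (any(raw$conditions$threshold_fit <= 0)) {
    stop("'threshold_fit' must be positive", call. = FALSE)
  }
  conditions <- raw$conditions
  conditions$drift <- conditions$drift_fit / conditions$threshold_fit
  conditions$diffusion_var <- 1 / conditions$threshold_fit^2
  structure(
    list(mouse_id = raw$mouse_id, conditions = conditions,
         start_bias = 2 * raw$start_fraction - 1,
         non_decision = raw$non_decision, threshold = 0.5,
         objective = raw$objective, n_evaluations = raw$n_evaluations,
         converged = raw$converged),
    class = "ddm_fit"
  )
}

#' Invert the rescaling identities
#'
#' @param fit A `ddm_fit` object.
#' @return The corresponding `ddm_fit_raw` (exact round trip).
#' @export
unscale_parameters <- function(fit) {
  if (!inherits(fit, "ddm_fit")) {
    stop("'fit' must be a 'ddm_fit' object", call. = FALSE)
  }
  conditions <- fit$conditions
  conditions$threshold_fit <- 1 / sqrt(conditions$diffusion_var)
  conditions$drift_fit <- conditions$drift * conditions$threshold_fit
  keep <- setdiff(names(conditions), c("drift", "diffusion_var"))
  structure(
    list(mouse_id = fit$mouse_id, conditions = conditions[, keep],
         start_fraction = (fit$start_bias + 1) / 2,
         non_decision = fit$non_decision, objective = fit$objective,
         n_evaluations = fit$n_evaluations, converged = fit$converged),
    class = "ddm_fit_raw"
  )
}

#' Extract one condition's parameters from a fit
#'
#' @param fit A `ddm_fit` object.
#' @param condition Condition key, e.g. `"A:3"` or `"none:2"`.
#' @return A [ddm_params()] object (threshold 1/2 convention, fitted
#'   non-decision time included).
#' @export
fit_condition_params <- function(fit, condition) {
  row <- fit$conditions[fit$conditions$condition == condition, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("fit does not cover condition '", condition, "'", call. = FALSE)
  }
  ddm_params(drift = row$drift, diffusion_var = row$diffusion_var,
             threshold = fit$threshold, start_bias = fit$start_bias,
             non_decision_time = fit$non_decision)
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf(
    "DDM chi-square fit, mouse %s: %d conditions, m = %.3f, Ter = %.3f s, objective = %.2f\n",
    x$mouse_id, nrow(x$conditions), x$start_bias, x$non_decision,
    x$objective))
  invisible(x)
}
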