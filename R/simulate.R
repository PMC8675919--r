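#' Simulate first-passage times of the decision process
#'
#' Euler-Maruyama integration of `dx/dt = A + xi` from `x = m * theta` until
#' `|x| >= theta`, with an exact within-step Brownian-bridge crossing test
#' (enabled by default) that removes the `O(sqrt(step))` first-passage bias
#' of the plain Euler scheme. Reproducible under `set.seed()`.
#'
#' @param params A [ddm_params()] object.
#' @param n Number of trials to simulate.
#' @param step Integration step in seconds.
#' @param crossing_correction Apply the within-step Brownian-bridge crossing
#'   test. Set to `FALSE` to expose the raw Euler scheme (used by step-size
#'   convergence checks).
#' @param max_time Guard against runaway trajectories: trials not absorbed
#'   by this time (seconds) are returned with `NA` entries.
#' @return A data frame with one row per trial: `boundary` (`"upper"` or
#'   `"lower"`) and `decision_time` (seconds, non-decision time not
#'   included).
#' @examples
#' set.seed(1)
#' sim <- simulate_first_passage(ddm_params(2, 3, 1), n = 100)
#' mean(sim$boundary == "upper")
#' @export
simulate_first_passage <- function(params, n = 1, step = 1e-4,
                                   crossing_correction = TRUE,
                                   max_time = 1e3) {
  .check_params(params)
  if (step <= 0) stop("'step' must be positive", call. = FALSE)
  res <- cpp_sim_fp(as.integer(n), params$drift, params$diffusion_var,
                    params$threshold, params$start_bias, step,
                    isTRUE(crossing_correction), max_time / step)
  data.frame(
    boundary = ifelse(is.na(res$upper), NA_character_,
                      ifelse(res$upper == 1L, "upper", "lower")),
    decision_time = res$decision_time,
    stringsAsFactors = FALSE
  )
}

#' Simulate a batch of responded trials with outlier contamination
#'
#' Each trial is, with probability `outlier_rate`, a contaminant that does
#' not follow the diffusion dynamics (e.g. an attentional lapse): its
#' reaction time is uniform on `[Ter, response_window]` and its response is a
#' coin flip between the two boundaries. All other trials are drawn from the
#' DDM, with reaction time = decision time + non-decision time. Trials whose
#' reaction time exceeds the response window are omitted from the returned
#' set, mirroring a task in which only responses inside the window are
#' recorded; the omission count is attached as attribute `"n_omitted"`.
#'
#' @inheritParams simulate_first_passage
#' @param outlier_rate Contamination probability in `[0, 1)`.
#' @param response_window Maximum reaction time in seconds (must exceed the
#'   non-decision time).
#' @return Data frame with columns `boundary`, `decision_time`,
#'   `reaction_time`, `is_outlier`; attribute `n_omitted` counts dropped
#'   over-window trials.
#' @export
simulate_trials <- function(params, n, outlier_rate = 0,
                            response_window = 2.8, step = 1e-4,
                            crossing_correction = TRUE) {
  .check_params(params)
  if (!is.numeric(outlier_rate) || outlier_rate < 0 || outlier_rate >= 1) {
    stop("'outlier_rate' must lie in [0, 1)", call. = FALSE)
  }
  ter <- params$non_decision_time
  if (response_window <= ter) {
    stop("'response_window' must exceed the non-decision time", call. = FALSE)
  }
  is_outlier <- runif(n) < outlier_rate
  n_out <- sum(is_outlier)
  boundary <- character(n)
  dt <- numeric(n)
  if (n_out > 0) {
    rt_out <- runif(n_out, ter, response_window)
    boundary[is_outlier] <- ifelse(runif(n_out) < 0.5, "upper", "lower")
    dt[is_outlier] <- rt_out - ter
  }
  if (n_out < n) {
    sim <- simulate_first_passage(params, n - n_out, step,
                                  crossing_correction)
    boundary[!is_outlier] <- sim$boundary
    dt[!is_outlier] <- sim$decision_time
  }
  out <- data.frame(boundary = boundary, decision_time = dt,
                    reaction_time = dt + ter, is_outlier = is_outlier,
                    stringsAsFactors = FALSE)
  keep <- !is.na(out$reaction_time) & out$reaction_time <= response_window
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_omitted") <- sum(!keep)
  res
}
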