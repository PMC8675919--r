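#' Background-interference hypothesis
#'
#' Describes one of three hypothesised mechanisms by which background
#' odorants degrade target detection, as a map from the number of background
#' odorants to DDM parameters:
#'
#' * `"false_signal"`: backgrounds add target-like evidence; the drift of
#'   both trial types increases by `background_function(n)`.
#' * `"signal_reduction"`: backgrounds suppress target-related signals; the
#'   drift of both trial types decreases by `background_function(n)`.
#' * `"noise_boost"`: backgrounds add diffusion noise; `background_function(n)`
#'   is added to the diffusion variance and drifts stay at baseline.
#'
#' Threshold and starting bias are never touched. Baselines must satisfy the
#' standing assumption that the target-off drift is negative and the
#' target-on drift positive in the absence of backgrounds.
#'
#' @param mechanism One of `"false_signal"`, `"signal_reduction"`,
#'   `"noise_boost"`.
#' @param baseline_on [ddm_params()] for target-on trials with no
#'   backgrounds (drift must be > 0).
#' @param baseline_off [ddm_params()] for target-off trials with no
#'   backgrounds (drift must be < 0). Must share threshold, start bias,
#'   diffusion variance and non-decision time with `baseline_on`.
#' @param background_gain Positive slope `k` of the default linear map from
#'   background count to parameter offset.
#' @param background_function Optional monotone nondecreasing function `f`
#'   with `f(0) = 0` replacing the default `f(n) = background_gain * n`; the
#'   qualitative predictions hold for any such function.
#' @return An object of class `hypothesis_spec`.
#' @examples
#' spec <- hypothesis_spec(
#'   "noise_boost",
#'   baseline_on = ddm_params(drift = 2, diffusion_var = 3),
#'   baseline_off = ddm_params(drift = -2.5, diffusion_var = 3)
#' )
#' prediction_table(spec, 0:6)
#' @export
hypothesis_spec <- function(mechanism = c("false_signal", "signal_reduction",
                                          "noise_boost"),
                            baseline_on, baseline_off,
                            background_gain = 1,
                            background_function = NULL) {
  mechanism <- match.arg(mechanism)
  .check_params(baseline_on)
  .check_params(baseline_off)
  if (baseline_on$drift <= 0 || baseline_off$drift >= 0) {
    stop("baseline drifts must satisfy drift(off) < 0 < drift(on)",
         call. = FALSE)
  }
  shared <- c("threshold", "start_bias", "diffusion_var", "non_decision_time")
  for (nm in shared) {
    if (!isTRUE(all.equal(baseline_on[[nm]], baseline_off[[nm]]))) {
      stop("baselines must share '", nm, "'", call. = FALSE)
    }
  }
  if (is.null(background_function)) {
    if (background_gain <= 0) {
      stop("'background_gain' must be positive", call. = FALSE)
    }
    force(background_gain)
    background_function <- function(n) background_gain * n
  } else {
    offs <- vapply(0:6, background_function, numeric(1))
    if (abs(offs[1]) > 1e-12 || any(diff(offs) < 0) || any(offs < 0)) {
      stop("'background_function' must be nonnegative, nondecreasing and 0 at 0",
           call. = FALSE)
    }
  }
  structure(
    list(mechanism = mechanism, baseline_on = baseline_on,
         baseline_off = baseline_off, background_gain = background_gain,
         background_function = background_function),
    class = "hypothesis_spec"
  )
}

#' Map a background count to condition parameters under a hypothesis
#'
#' @param spec A [hypothesis_spec()].
#' @param n_background Nonnegative integer count of background odorants.
#' @param trial_type `"target_on"` or `"target_off"`.
#' @return A [ddm_params()] object for the condition. Under
#'   `"signal_reduction"` the target-on drift may become negative at high
#'   background counts (the choice probability then falls below the unbiased
#'   chance level); only the baselines are sign-constrained.
#' @export
apply_mechanism <- function(spec, n_background,
                            trial_type = c("target_on", "target_off")) {
  if (!inherits(spec, "hypothesis_spec")) {
    stop("'spec' must be a 'hypothesis_spec' object", call. = FALSE)
  }
  trial_type <- match.arg(trial_type)
  if (!is.numeric(n_background) || length(n_background) != 1L ||
      n_background < 0 || n_background != round(n_background)) {
    stop("'n_background' must be a single nonnegative integer", call. = FALSE)
  }
  base <- if (trial_type == "target_on") spec$baseline_on else
    spec$baseline_off
  off <- spec$background_function(n_background)
  switch(spec$mechanism,
    false_signal = ddm_params(
      drift = base$drift + off, diffusion_var = base$diffusion_var,
      threshold = base$threshold, start_bias = base$start_bias,
      non_decision_time = base$non_decision_time),
    signal_reduction = ddm_params(
      drift = base$drift - off, diffusion_var = base$diffusion_var,
      threshold = base$threshold, start_bias = base$start_bias,
      non_decision_time = base$non_decision_time),
    noise_boost = ddm_params(
      drift = base$drift, diffusion_var = base$diffusion_var + off,
      threshold = base$threshold, start_bias = base$start_bias,
      non_decision_time = base$non_decision_time)
  )
}

#' Prediction curves of a background-interference hypothesis
#'
#' Evaluates the closed-form choice probability and mean decision time at
#' every background count for both trial types, producing the
#' accuracy-vs-background and speed-vs-background curves that distinguish
#' the three mechanisms: under `"false_signal"` the probability of reporting
#' "target present" rises with background count in both trial types, under
#' `"signal_reduction"` it falls in both, and under `"noise_boost"` it
#' contracts toward the stimulus-independent level `(1 + m)/2` while the
#' mean decision time shrinks in both trial types.
#'
#' @inheritParams apply_mechanism
#' @param n_background Integer vector of background counts.
#' @return A data frame with columns `mechanism`, `n_background`,
#'   `trial_type`, `p` (probability of reporting target present) and
#'   `mean_dt` (mean decision time, seconds).
#' @export
prediction_table <- function(spec, n_background = 0:6) {
  rows <- expand.grid(n_background = n_background,
                      trial_type = c("target_on", "target_off"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    pars <- apply_mechanism(spec, rows$n_background[i], rows$trial_type[i])
    data.frame(mechanism = spec$mechanism,
               n_background = rows$n_background[i],
               trial_type = rows$trial_type[i],
               p = choice_probability(pars),
               mean_dt = mean_decision_time(pars))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
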