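#' DDM parameter set for a single condition
#'
#' Bundles the five parameters of the drift-diffusion process used throughout
#' the package: a decision variable `x` starts at `start_bias * threshold`,
#' drifts at rate `drift` while accumulating white noise of variance
#' `diffusion_var` per unit time, and a response is emitted when `x` first
#' reaches `+threshold` ("report target present") or `-threshold`
#' ("report target absent"). `non_decision_time` is the reaction-time
#' component outside the diffusion process (sensory and motor delays).
#'
#' @param drift Mean evidence-accumulation rate `A` (evidence units/second).
#'   Positive values favour the upper ("target present") threshold.
#' @param diffusion_var Variance `c^2` of the accumulated white noise per unit
#'   time (evidence^2/second). Must be positive.
#' @param threshold Threshold magnitude `theta > 0`; the absorbing boundaries
#'   sit at `+theta` and `-theta`.
#' @param start_bias Dimensionless starting-point bias `m` in (-1, 1); the
#'   process starts at `m * theta`. `m = 0` is unbiased.
#' @param non_decision_time Non-decision time `Ter` in seconds (>= 0).
#'
#' @return An object of class `ddm_params` (a named list).
#' @examples
#' p <- ddm_params(drift = 2, diffusion_var = 3, threshold = 1)
#' choice_probability(p)
#' @export
ddm_params <- function(drift, diffusion_var = 1, threshold = 1,
                       start_bias = 0, non_decision_time = 0) {
  for (nm in c("drift", "diffusion_var", "threshold", "start_bias",
               "non_decision_time")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    }
  }
  if (threshold <= 0) stop("'threshold' must be > 0", call. = FALSE)
  if (diffusion_var <= 0) stop("'diffusion_var' must be > 0", call. = FALSE)
  if (abs(start_bias) >= 1) {
    stop("'start_bias' must lie in the open interval (-1, 1)", call. = FALSE)
  }
  if (non_decision_time < 0) {
    stop("'non_decision_time' must be >= 0", call. = FALSE)
  }
  structure(
    list(drift = drift, diffusion_var = diffusion_var, threshold = threshold,
         start_bias = start_bias, non_decision_time = non_decision_time),
    class = "ddm_params"
  )
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "DDM parameters: A = %g, c2 = %g, theta = %g, m = %g, Ter = %g s\n",
    x$drift, x$diffusion_var, x$threshold, x$start_bias,
    x$non_decision_time))
  invisible(x)
}

.check_params <- function(params) {
  if (!inherits(params, "ddm_params")) {
    stop("'params' must be a 'ddm_params' object", call. = FALSE)
  }
  params
}

#' Scaled drift r = 2 A theta / c^2
#'
#' The dimensionless combination of drift, threshold and diffusion variance
#' that, together with the starting-point bias, fully determines the choice
#' probability.
#'
#' @param params A [ddm_params()] object.
#' @return The scalar `r`; zero when `drift` is zero.
#' @export
scaled_drift <- function(params) {
  .check_params(params)
  2 * params$drift * params$threshold / params$diffusion_var
}
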