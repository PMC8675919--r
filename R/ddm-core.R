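#' @name ddm-closed-forms
#' @title Closed-form choice probability and timing of the two-boundary DDM
#'
#' @description
#' For a diffusion `dx/dt = A + xi` with `E[xi(t) xi(t')] = c^2 delta(t-t')`,
#' absorbing boundaries at `+theta`/`-theta` and start point `m*theta`, the
#' probability of first reaching `+theta` is
#' `p = (exp(r) - exp(-r m)) / (2 sinh(r))` and the mean decision time is
#' `E[DT] = theta * (cosh(r) - m*sinh(r) - exp(-r m)) / (A * sinh(r))`, with
#' `r = 2 A theta / c^2`. Both expressions are evaluated in numerically
#' stable scaled forms, and the `r -> 0` limits (`(1+m)/2` and the
#' pure-diffusion exit time `theta^2 (1 - m^2)/c^2`) are used when
#' `|r| < 1e-6`.
NULL

# threshold below which r is treated as zero (limit branches)
.R_EPS <- 1e-6

# p(upper first) as a function of r and m; exact rewrite of
# (e^r - e^{-rm}) / (2 sinh r) that only ever exponentiates negative
# quantities:  p = (1 - e^{-r(1+m)}) / (1 - e^{-2r})  for r > 0,
# with p(r, m) = 1 - p(-r, -m) for r < 0.  Vectorized over r.
.p_upper <- function(r, m) {
  p <- numeric(length(r))
  z <- abs(r) < .R_EPS
  p[z] <- (1 + m) / 2
  pos <- !z & r > 0
  neg <- !z & r < 0
  if (any(pos)) {
    p[pos] <- -expm1(-r[pos] * (1 + m)) / -expm1(-2 * r[pos])
  }
  if (any(neg)) {
    p[neg] <- 1 + expm1(r[neg] * (1 - m)) / -expm1(2 * r[neg])
  }
  p
}

# E[DT] in units where theta/A multiplies a function of (r, m); stable
# scaled form for r > 0, reflection E(A, m) = E(-A, -m) for r < 0.
.mean_dt_rm <- function(r, m, theta, drift, diffusion_var) {
  if (abs(r) < .R_EPS) {
    return(theta^2 * (1 - m^2) / diffusion_var)
  }
  if (r < 0) {
    return(.mean_dt_rm(-r, -m, theta, -drift, diffusion_var))
  }
  (theta / drift) *
    ((1 - m) + (1 + m) * exp(-2 * r) - 2 * exp(-r * (1 + m))) /
    (1 - exp(-2 * r))
}

#' Choice probability of the upper ("target present") threshold
#'
#' @param params A [ddm_params()] object.
#' @return Probability in (0, 1) that the decision variable is absorbed at
#'   `+threshold` before `-threshold`. At `r = 0` (zero drift) the continuous
#'   limit `(1 + m)/2` is returned.
#' @seealso [mean_decision_time()], [choice_probability_derivatives()]
#' @rdname ddm-closed-forms
#' @export
choice_probability <- function(params) {
  .check_params(params)
  .p_upper(scaled_drift(params), params$start_bias)
}

#' Mean decision time
#'
#' @return `mean_decision_time()`: the expected first-passage time E[DT] in
#'   seconds (non-decision time not included).
#' @rdname ddm-closed-forms
#' @export
mean_decision_time <- function(params) {
  .check_params(params)
  .mean_dt_rm(scaled_drift(params), params$start_bias, params$threshold,
              params$drift, params$diffusion_var)
}

#' Sensitivity factor g(r)
#'
#' `g(r) = exp(-r m) * (cosh(r) + m * sinh(r)) - 1` is the common factor of
#' the derivatives of the choice probability and mean decision time with
#' respect to the drift and the diffusion variance. It vanishes at `r = 0`
#' and is strictly positive elsewhere for `|m| < 1`, which pins down the sign
#' of all three derivatives.
#'
#' @param r Scaled drift (any real; vectorized).
#' @param m Starting-point bias in (-1, 1).
#' @return `g(r)`, a nonnegative number.
#' @export
g_factor <- function(r, m) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || abs(m) >= 1) {
    stop("'m' must be a single number in (-1, 1)", call. = FALSE)
  }
  out <- numeric(length(r))
  small <- abs(r) < 1e-3
  if (any(small)) {
    # series around r = 0 avoids cancellation:
    # g = (1 - m^2) (r^2/2 - m r^3/3 + O(r^4))
    rs <- r[small]
    out[small] <- (1 - m^2) * (rs^2 / 2 - m * rs^3 / 3)
  }
  if (any(!small)) {
    rl <- r[!small]
    out[!small] <- exp(-rl * m) * (cosh(rl) + m * sinh(rl)) - 1
  }
  out
}

# g(r) / sinh(r)^2, stable for all r != 0.  Uses the symmetry
# ratio(r, m) = ratio(-r, -m) and, for r > 0, the exact scaled form
#   4 * ( ((1+m) e^{-r(1+m)} + (1-m) e^{-r(3+m)}) / 2 - e^{-2r} )
#       / (1 - e^{-2r})^2
.g_over_sinh2 <- function(r, m) {
  if (abs(r) < .R_EPS) {
    stop("derivatives are undefined at r = 0; handle the limit separately",
         call. = FALSE)
  }
  if (r < 0) return(.g_over_sinh2(-r, -m))
  if (r < 1e-3) {
    # both numerator and denominator are O(r^2); take the series ratio
    return((1 - m^2) * (1 / 2 - m * r / 3) / (1 + r^2 / 3))
  }
  num <- ((1 + m) * exp(-r * (1 + m)) + (1 - m) * exp(-r * (3 + m))) / 2 -
    exp(-2 * r)
  4 * num / (1 - exp(-2 * r))^2
}

#' Derivatives of the choice probability
#'
#' Partial derivatives of the upper-threshold choice probability with respect
#' to the drift rate and the diffusion variance:
#' `dp/dA = theta g(r) / (c^2 sinh^2 r)` (always positive) and
#' `dp/dc2 = -A theta g(r) / (c^4 sinh^2 r)` (opposite in sign to `A`).
#'
#' @param params A [ddm_params()] object with nonzero scaled drift.
#' @return A list with elements `dp_dA` and `dp_dc2`.
#' @export
choice_probability_derivatives <- function(params) {
  .check_params(params)
  r <- scaled_drift(params)
  ratio <- .g_over_sinh2(r, params$start_bias)
  list(
    dp_dA = params$threshold * ratio / params$diffusion_var,
    dp_dc2 = -params$drift * params$threshold * ratio /
      params$diffusion_var^2
  )
}

#' Derivative of the mean decision time with respect to the diffusion variance
#'
#' `dE[DT]/dc2 = -2 theta^2 g(r) / (c^4 sinh^2 r)`, strictly negative for
#' `r != 0`: added diffusion noise always speeds decisions up, whatever the
#' drift sign or starting bias. This is the closed-form basis of the
#' noise-boost prediction that harder (noisier) trials are answered faster.
#'
#' @inheritParams choice_probability_derivatives
#' @return A negative scalar.
#' @export
mean_dt_derivative_c2 <- function(params) {
  .check_params(params)
  r <- scaled_drift(params)
  ratio <- .g_over_sinh2(r, params$start_bias)
  -2 * params$threshold^2 * ratio / params$diffusion_var^2
}
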