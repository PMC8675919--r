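#' @name fpt
#' @title Defective first-passage-time distributions
#'
#' @description
#' Cumulative probability that the decision variable is absorbed at a given
#' threshold *and* that this happens by decision time `t`. Each boundary's
#' distribution is "defective": it saturates at that boundary's choice
#' probability rather than at 1.
#'
#' Internally the process is mapped to a unit-diffusion Wiener process on
#' `[0, a]` with `a = 2 theta / c`, start `z = (1 + m) theta / c` and drift
#' `v = A / c`. Two classical series represent the lower-boundary defective
#' CDF: a spectral ("large-time") sine series whose terms decay like
#' `exp(-k^2 pi^2 t / (2 a^2))`, and a method-of-images ("small-time") sum of
#' Gaussian-tail terms. The representation is chosen per evaluation point by
#' the standardized time `t / a^2`, and each series is truncated once terms
#' fall below 1e-9 relative to machine-level accuracy of the running sum.
NULL

# lower-boundary defective CDF on [0, a]: spectral series
# F0(t) = P0 - (pi/a^2) e^{-v z} sum_k k sin(k pi z / a) e^{-lambda_k t} / lambda_k
.fpt_lower_large <- function(t, v, a, z) {
  # total lower-boundary mass P0 = (e^{-2vz} - e^{-2va}) / (1 - e^{-2va}),
  # rewritten so that only negative quantities are exponentiated
  P0 <- if (abs(v * a) < 1e-12) {
    1 - z / a
  } else if (v > 0) {
    (exp(-2 * v * z) - exp(-2 * v * a)) / -expm1(-2 * v * a)
  } else {
    expm1(2 * v * (a - z)) / expm1(2 * v * a)
  }
  # number of terms needed at the smallest t
  tmin <- max(min(t), 1e-8)
  K <- ceiling(a / pi * sqrt(2 * 30 / tmin)) + 8L
  k <- seq_len(K)
  lam <- (v^2 + (k * pi / a)^2) / 2
  # exponentials combined in log space so strong drifts cannot overflow
  lbase <- log(pi / a^2) + log(k) - log(lam) - v * z
  sgn <- sin(k * pi * z / a)
  vapply(t, function(tt) {
    P0 - sum(sgn * exp(lbase - lam * tt))
  }, numeric(1))
}

# lower-boundary defective CDF: method-of-images series, stable in log space.
# F0(t) = sum_k [ e^{2kav} Phi((-v t - d_k)/sqrt t)
#               + e^{-2kav - 2vz} Phi((v t - d_k)/sqrt t) ]  (d_k = 2ka + z)
# minus, for images with d_k <= 0, the t -> 0 constants e^{2kav} and
# e^{-2kav - 2vz}.
.fpt_lower_small <- function(t, v, a, z) {
  vapply(t, function(tt) {
    if (tt <= 0) return(0)
    st <- sqrt(tt)
    total <- 0
    for (k in 0:200) {
      inc <- 0
      for (kk in unique(c(k, -k))) {
        d <- 2 * kk * a + z
        if (d > 0) {
          l1 <- 2 * kk * a * v + pnorm((-v * tt - d) / st, log.p = TRUE)
          l2 <- -2 * kk * a * v - 2 * v * z + pnorm((v * tt - d) / st,
                                                    log.p = TRUE)
          term <- exp(l1) + exp(l2)
        } else {
          # subtract the t -> 0 constants in log space (Phi(x) - 1 = -Phi(-x))
          l1 <- 2 * kk * a * v + pnorm((v * tt + d) / st, log.p = TRUE)
          l2 <- -2 * kk * a * v - 2 * v * z + pnorm((d - v * tt) / st,
                                                    log.p = TRUE)
          term <- -exp(l1) - exp(l2)
        }
        inc <- inc + term
      }
      total <- total + inc
      if (k > 0 && abs(inc) < 1e-12) break
    }
    total
  }, numeric(1))
}

# defective CDF at the lower boundary of the [0, a] process, switching
# representation on standardized time
.fpt_lower <- function(t, v, a, z) {
  out <- numeric(length(t))
  tau <- t / a^2
  small <- tau < 0.1
  if (any(small & t > 0)) {
    idx <- small & t > 0
    out[idx] <- .fpt_lower_small(t[idx], v, a, z)
  }
  if (any(!small)) out[!small] <- .fpt_lower_large(t[!small], v, a, z)
  pmin(pmax(out, 0), 1)
}

# core defective CDF in model coordinates (decision-time scale, vectorized
# over t); upper boundary obtained from the lower one by reflection
.fpt_cdf_core <- function(t, drift, diffusion_var, threshold, start_bias,
                          upper) {
  cc <- sqrt(diffusion_var)
  a <- 2 * threshold / cc
  z <- (1 + start_bias) * threshold / cc
  v <- drift / cc
  if (upper) .fpt_lower(t, -v, a, a - z) else .fpt_lower(t, v, a, z)
}

#' @param params A [ddm_params()] object.
#' @param t Vector of decision times in seconds (>= 0). The non-decision time
#'   is *not* included: `t` is on the diffusion clock.
#' @param boundary `"upper"` (report target present) or `"lower"`.
#' @return `fpt_defective_cdf()`: P(absorbed at `boundary` and decision time
#'   <= `t`), nondecreasing in `t`, saturating at the boundary's choice
#'   probability.
#' @examples
#' p <- ddm_params(drift = 2, diffusion_var = 3, threshold = 1)
#' fpt_defective_cdf(p, c(0.1, 0.5, 2), "upper")
#' @rdname fpt
#' @export
fpt_defective_cdf <- function(params, t, boundary = c("upper", "lower")) {
  .check_params(params)
  boundary <- match.arg(boundary)
  if (any(!is.finite(t) & !is.infinite(t)) || any(t < 0)) {
    stop("'t' must be nonnegative", call. = FALSE)
  }
  out <- numeric(length(t))
  inf <- is.infinite(t)
  if (any(inf)) {
    mass <- .p_upper(scaled_drift(params), params$start_bias)
    out[inf] <- if (boundary == "upper") mass else 1 - mass
  }
  if (any(!inf)) {
    out[!inf] <- .fpt_cdf_core(t[!inf], params$drift, params$diffusion_var,
                               params$threshold, params$start_bias,
                               boundary == "upper")
  }
  out
}

#' @param prob Cumulative fraction(s) in (0, 1) of the boundary's total
#'   (defective) mass.
#' @param tol Absolute bisection tolerance on the returned time, seconds.
#' @return `fpt_quantile()`: decision time(s) `t` such that the boundary's
#'   defective CDF equals `prob` times the boundary's total mass (i.e.
#'   quantiles of the *conditional* first-passage-time distribution at that
#'   boundary), found by monotone bisection.
#' @rdname fpt
#' @export
fpt_quantile <- function(params, prob, boundary = c("upper", "lower"),
                         tol = 1e-8) {
  .check_params(params)
  boundary <- match.arg(boundary)
  if (any(prob <= 0 | prob >= 1)) {
    stop("'prob' must lie strictly between 0 and 1", call. = FALSE)
  }
  mass <- fpt_defective_cdf(params, Inf, boundary)
  vapply(prob, function(p0) {
    target <- p0 * mass
    hi <- 1
    while (.fpt_cdf_core(hi, params$drift, params$diffusion_var,
                         params$threshold, params$start_bias,
                         boundary == "upper") < target && hi < 1e6) {
      hi <- hi * 2
    }
    lo <- 0
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      val <- .fpt_cdf_core(mid, params$drift, params$diffusion_var,
                           params$threshold, params$start_bias,
                           boundary == "upper")
      if (val < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}
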