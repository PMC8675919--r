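test_that("parameter validation enforces the model's domain", {
  expect_error(ddm_params(1, diffusion_var = 0), "diffusion_var")
  expect_error(ddm_params(1, threshold = -1), "threshold")
  expect_error(ddm_params(1, start_bias = 1), "start_bias")
  expect_error(ddm_params(1, non_decision_time = -0.1), "non_decision")
  expect_equal(scaled_drift(ddm_params(2, 3, 1)), 4 / 3)
  expect_equal(scaled_drift(ddm_params(0, 3, 1)), 0)
  expect_equal(scaled_drift(ddm_params(-2.5, 3, 1)), -5 / 3)
})

test_that("choice probability matches the closed form and its limits", {
  # symmetric zero-drift limit and the stimulus-independent level (1+m)/2
  expect_equal(choice_probability(ddm_params(0, 3, 1)), 0.5)
  expect_equal(choice_probability(ddm_params(0, 3, 1, start_bias = 0.2)),
               0.6)
  for (m in c(-0.9, -0.3, 0, 0.4, 0.9)) {
    expect_equal(choice_probability(ddm_params(0, 2, 1, m)), (1 + m) / 2,
                 tolerance = 1e-10)
    # approach of the limit branch from tiny nonzero drift
    expect_equal(choice_probability(ddm_params(1e-9, 2, 1, m)), (1 + m) / 2,
                 tolerance = 1e-7)
  }
  # naive evaluation of (e^r - e^{-rm}) / (2 sinh r) at moderate r
  naive <- function(A, c2, th, m) {
    r <- 2 * A * th / c2
    (exp(r) - exp(-r * m)) / (2 * sinh(r))
  }
  for (p in reference_params()) {
    expect_equal(choice_probability(p),
                 naive(p$drift, p$diffusion_var, p$threshold, p$start_bias),
                 tolerance = 1e-12)
  }
  # stability where naive evaluation overflows
  expect_equal(choice_probability(ddm_params(500, 1, 1)), 1,
               tolerance = 1e-10)
  expect_gt(choice_probability(ddm_params(500, 1, 1)), 0)
  expect_lt(choice_probability(ddm_params(-500, 1, 1)), 1e-10)
})

test_that("mean decision time obeys the m = 0 identity and reflection", {
  # at m = 0 the closed form collapses to (theta/A) tanh(r/2)
  for (A in c(-2.5, -1, 0.5, 2)) {
    p <- ddm_params(A, 3, 1)
    r <- scaled_drift(p)
    expect_equal(mean_decision_time(p), (1 / A) * tanh(r / 2),
                 tolerance = 1e-12)
  }
  # reflection symmetry E[DT](A, m) = E[DT](-A, -m)
  for (p in reference_params()) {
    q <- ddm_params(-p$drift, p$diffusion_var, p$threshold, -p$start_bias)
    expect_equal(mean_decision_time(p), mean_decision_time(q),
                 tolerance = 1e-12)
  }
  # zero-drift limit is the pure-diffusion exit time theta^2 (1 - m^2) / c2
  expect_equal(mean_decision_time(ddm_params(0, 1, 1, 0.5)),
               1 * (1 - 0.25) / 1, tolerance = 1e-10)
  expect_equal(mean_decision_time(ddm_params(1e-9, 2, 1.5)), 1.5^2 / 2,
               tolerance = 1e-6)
})

test_that("g factor vanishes only at r = 0 and is positive elsewhere", {
  for (m in c(-0.9, 0, 0.9)) {
    expect_equal(g_factor(0, m), 0)
    for (r in c(-5, -1, -0.1, 0.1, 1, 5)) expect_gt(g_factor(r, m), 0)
  }
  expect_equal(g_factor(1, 0), cosh(1) - 1, tolerance = 1e-12)
  # series branch continuous with direct evaluation
  direct <- function(r, m) exp(-r * m) * (cosh(r) + m * sinh(r)) - 1
  expect_equal(g_factor(9e-4, 0.5), direct(9e-4, 0.5), tolerance = 1e-6)
  expect_error(g_factor(1, 1), "m")
})

test_that("derivatives match central finite differences and carry the right signs", {
  fd <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
  for (p in reference_params()) {
    d <- choice_probability_derivatives(p)
    fda <- fd(function(a) choice_probability(
      ddm_params(a, p$diffusion_var, p$threshold, p$start_bias)), p$drift)
    fdc <- fd(function(c2) choice_probability(
      ddm_params(p$drift, c2, p$threshold, p$start_bias)), p$diffusion_var)
    expect_equal(d$dp_dA, fda, tolerance = 1e-4)
    expect_equal(d$dp_dc2, fdc, tolerance = 1e-4)
    expect_gt(d$dp_dA, 0)
    expect_equal(sign(d$dp_dc2), -sign(p$drift))
    dE <- mean_dt_derivative_c2(p)
    fde <- fd(function(c2) mean_decision_time(
      ddm_params(p$drift, c2, p$threshold, p$start_bias)), p$diffusion_var)
    expect_equal(dE, fde, tolerance = 1e-4)
    expect_lt(dE, 0)
  }
  expect_error(choice_probability_derivatives(ddm_params(0, 3, 1)), "r = 0")
  expect_error(mean_dt_derivative_c2(ddm_params(0, 3, 1)), "r = 0")
})

test_that("choice probability increases in drift; mean DT decreases in diffusion", {
  for (m in c(-0.4, 0, 0.4)) {
    for (c2 in c(0.5, 2, 5)) {
      A <- seq(-4, 4, length.out = 21)
      ps <- vapply(A, function(a) choice_probability(
        ddm_params(a, c2, 1, m)), numeric(1))
      expect_true(all(diff(ps) > 0))
      c2s <- seq(0.5, 8, length.out = 16)
      es <- vapply(c2s, function(cc) mean_decision_time(
        ddm_params(1.5, cc, 1, m)), numeric(1))
      expect_true(all(diff(es) < 0))
    }
  }
})
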