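fig_rates <- rate_set(k_init = 0.5, k_pre = 1.7, k_rel = 0.25,
                      k_elong = 2000)

test_that("steady state matches the closed form and is linear in k_init", {
  ss <- steady_state(fig_rates)
  expect_equal(ss$p, 0.5 / 1.95, tolerance = 1e-12)
  expect_equal(ss$b, 0.25 / 2000 * 0.5 / 1.95, tolerance = 1e-12)
  # hand-computed reference values
  expect_equal(ss$p, 0.25641, tolerance = 1e-4)
  expect_equal(ss$b, 3.2051e-5, tolerance = 1e-4)

  expect_equal(steady_state(rate_set(1, 0, 1, 1)), list(p = 1, b = 1))

  doubled <- steady_state(rate_set(1.0, 1.7, 0.25, 2000))
  expect_equal(doubled$p, 2 * steady_state(rate_set(0.5, 1.7, 0.25, 2000))$p)
  expect_equal(doubled$b, 2 * steady_state(rate_set(0.5, 1.7, 0.25, 2000))$b)

  expect_error(steady_state(rate_set(1, 0, 0, 1)), "degenerate")
  expect_error(rate_set(-1, 0, 1, 1), ">= 0")
})

test_that("trajectories converge to the steady state and decay correctly", {
  # no flux: constant trajectory
  tr <- simulate_pause_body(rate_set(0, 0, 0, 0), 0.3, 0.1, 10, 1)
  expect_true(all(tr$p == 0.3))
  expect_true(all(tr$b == 0.1))

  # convergence from empty gene to the analytic steady state
  tr <- simulate_pause_body(fig_rates, 0, 0, 60, 1)
  fin <- tr[nrow(tr), ]
  ss <- steady_state(fig_rates)
  expect_equal(fin$p, ss$p, tolerance = 1e-6)
  expect_equal(fin$b, ss$b, tolerance = 1e-6)

  # shutting off initiation: pure exponential decay of the pause peak
  r0 <- rate_set(0, 1.7, 0.25, 2000)
  tr <- simulate_pause_body(r0, ss$p, ss$b, 2, 0.25)
  expect_equal(tr$p, ss$p * exp(-1.95 * tr$time), tolerance = 1e-12)
})

test_that("closed-form trajectories agree with a numeric integrator", {
  skip_if_not_installed("deSolve")
  set.seed(11)
  for (i in 1:5) {
    k <- rate_set(runif(1, 0.1, 2), runif(1, 0.1, 3), runif(1, 0.1, 2),
                  runif(1, 500, 4000))
    p0 <- runif(1, 0, 1); b0 <- runif(1, 0, 1e-3)
    ode <- deSolve::ode(
      y = c(p = p0, b = b0), times = seq(0, 5, by = 0.5),
      func = function(t, y, parms) {
        list(c(k$k_init - (k$k_pre + k$k_rel) * y[1],
               k$k_rel * y[1] - k$k_elong * y[2]))
      }, parms = NULL, rtol = 1e-10, atol = 1e-12)
    tr <- simulate_pause_body(k, p0, b0, 5, 0.5)
    expect_equal(tr$p, unname(ode[, "p"]), tolerance = 1e-6)
    expect_equal(tr$b, unname(ode[, "b"]), tolerance = 1e-6)
  }
  # degenerate case: total pause exit rate equals the elongation rate
  k <- rate_set(1, 0.6, 0.4, 1)
  ode <- deSolve::ode(
    y = c(p = 0.2, b = 0.1), times = seq(0, 5, by = 0.5),
    func = function(t, y, parms) {
      list(c(1 - 1 * y[1], 0.4 * y[1] - 1 * y[2]))
    }, parms = NULL, rtol = 1e-10, atol = 1e-12)
  tr <- simulate_pause_body(k, 0.2, 0.1, 5, 0.5)
  expect_equal(tr$b, unname(ode[, "b"]), tolerance = 1e-6)
})

test_that("fold change relations follow the pausing index", {
  expect_equal(fold_change_pause_release(2, 1), 2)
  expect_equal(fold_change_pause_release(0.15, 0.3), 0.5)
  x <- c(0.2, 1, 7)
  expect_equal(fold_change_pause_release(x, x), rep(1, 3))
  expect_error(fold_change_pause_release(-1, 1), "> 0")

  b <- fold_change_initiation_bounds(0.3, 0.15)
  expect_equal(b$lower, 0.15); expect_equal(b$upper, 0.3)
  b <- fold_change_initiation_bounds(0.25, 0.25)
  expect_equal(b$lower, b$upper)
  b <- fold_change_initiation_bounds(0.5, 1.2)
  expect_equal(c(b$lower, b$upper), c(0.5, 1.2))
})

test_that("initiation fold change interpolates its bounds in r", {
  expect_equal(fold_change_initiation_given_ratio(0.3, 0.5, 1e9), 0.3,
               tolerance = 1e-8)
  expect_equal(fold_change_initiation_given_ratio(0.3, 0.5, 0), 0.15)
  expect_equal(fold_change_initiation_given_ratio(0.3, 0.5, 2), 0.25)

  # monotone in r, always inside the bounds
  set.seed(21)
  for (i in 1:50) {
    fc_p <- rlnorm(1); fc_krel <- rlnorm(1)
    rr <- sort(rlnorm(10, 0, 2))
    v <- fold_change_initiation_given_ratio(fc_p, fc_krel, rr)
    bounds <- fold_change_initiation_bounds(fc_p, fc_p * fc_krel)
    expect_true(all(v >= bounds$lower - 1e-12 & v <= bounds$upper + 1e-12))
    d <- diff(v)
    expect_true(all(d >= -1e-12) || all(d <= 1e-12))  # monotone
  }
})

test_that("absolute pause release rate is a scale-free density ratio", {
  expect_equal(pause_release_rate(2000, 50, 0.0215), 0.86)
  expect_equal(pause_release_rate(1000, 10, 0), 0)
  s <- 37.3
  expect_equal(pause_release_rate(2000, 50 * s, 0.0215 * s), 0.86)
  expect_equal(pause_release_rate(4000, 50, 0.0215),
               2 * pause_release_rate(2000, 50, 0.0215))
  expect_error(pause_release_rate(2000, 0, 1), "pause density")
})

test_that("absolute initiation rate inverts the steady state", {
  expect_equal(initiation_rate(0.5 / 1.95, 0.25 / 2000 * 0.5 / 1.95,
                               1.7, 2000), 0.5, tolerance = 1e-12)
  expect_equal(initiation_rate(0.3, 0, 2, 1000), 0.6)
  expect_equal(initiation_rate(0, 0, 1, 1000), 0)
  expect_error(initiation_rate(1.2, 1e-5, 1.7, 2000), "\\[0, 1\\]")
  expect_error(initiation_rate(0.3, 1e-5, 1.7, 2000, scaled = FALSE),
               "occupancy-scaled")
})

test_that("effective release, spacing and half-life track occupancies", {
  expect_equal(effective_pause_release(1.35, 0.25), 0.3375)
  expect_equal(effective_pause_release(3, 0), 0)
  expect_equal(effective_pause_release(0.25, 0.25641), 0.0641,
               tolerance = 1e-3)
  expect_error(effective_pause_release(1, 1.2), "\\[0, 1\\]")

  expect_equal(polymerase_spacing(1 / 9600), 9600)
  expect_equal(polymerase_spacing(3.2051e-5), 31200, tolerance = 1e-4)
  expect_equal(polymerase_spacing(0), Inf)
  b <- 1e-4; s <- 5
  expect_equal(polymerase_spacing(s * b), polymerase_spacing(b) / s)

  expect_equal(pause_half_life(log(2) / 2, log(2) / 2), 60)
  expect_equal(pause_half_life(6.7 * 0.86, 0.86), 6.28, tolerance = 1e-2)
  expect_equal(pause_half_life(1.7, 0.25), 21.3, tolerance = 1e-2)
  expect_equal(pause_half_life(0, 0), Inf)
})

test_that("termination/release ratio recovers r and flags boundaries", {
  tr <- termination_release_ratio(0.5, 0.25, 0.3)
  expect_equal(tr$ratio, 2, tolerance = 1e-9)
  expect_equal(tr$status, "ok")

  # fc_kinit at the body bound: ratio exactly zero
  tr <- termination_release_ratio(0.5, 0.5 * 0.3, 0.3)
  expect_equal(tr$status, "zero_boundary")
  expect_equal(tr$ratio, 0)

  # fc_kinit at the pause bound: undefined
  tr <- termination_release_ratio(0.5, 0.3, 0.3)
  expect_equal(tr$status, "undefined_boundary")
  expect_true(is.na(tr$ratio))

  # fc_kinit outside the bounds: negative, flagged not clipped
  tr <- termination_release_ratio(0.5, 0.45, 0.3)  # X = 1.5 > 1, fc_krel < X
  expect_equal(tr$status, "negative")
  expect_true(tr$ratio < 0)

  # forward-model round trip at modest n (full scale in the acceptance
  # suite): generated r is recovered through Eq-5 steady states
  set.seed(31)
  for (i in 1:50) {
    k_pre <- rlnorm(1, 0, 1); k_rel <- rlnorm(1, 0, 1)
    fc_krel <- rlnorm(1, 0, 0.5); fc_kinit <- rlnorm(1, 0, 0.5)
    fw <- forward_densities(1, k_pre, k_rel, 2000, fc_kinit, fc_krel)
    out <- termination_release_ratio(fc_krel, fc_kinit, fw$fc_p)
    expect_equal(out$ratio, k_pre / k_rel, tolerance = 1e-8)
  }
})
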