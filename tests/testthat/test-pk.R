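test_that("Bateman solution honors initial condition and no-clearance limit", {
  p <- pk_params(0.02, 0.001)
  sol <- solve_two_compartment(p, times = c(-50, 0, 10), t_fd = 0)
  expect_equal(sol$m_iv[1:2], c(0, 0))    # pre-injection and tau = 0
  p0 <- pk_params(0.02, 0)                # no clearance: everything ends up in blood
  sol0 <- solve_two_compartment(p0, times = 3000, t_fd = 0)
  expect_equal(sol0$m_iv, p0$dose, tolerance = 1e-8)
})

test_that("intravascular peak time matches a brute-force argmax of the closed form", {
  p <- pk_params(0.02, 0.001)
  tau_grid <- seq(0, 1000, by = 0.01)
  m <- solve_two_compartment(p, tau_grid, t_fd = 0)$m_iv
  tau_star_brute <- tau_grid[which.max(m)]
  expect_equal(tau_star_brute, 157.67, tolerance = 1e-4)
  expect_equal(pk_peak_time(p), log(p$k_a / p$k_e) / (p$k_a - p$k_e))
  expect_equal(pk_peak_time(p), tau_star_brute, tolerance = 1e-4)
})

test_that("closed form agrees with an independent stiff ODE integrator", {
  skip_if_not_installed("deSolve")
  set.seed(101)
  for (i in 1:100) {
    k_a <- stats::runif(1, 1e-3, 0.1)
    k_e <- stats::runif(1, 1e-5, 0.05)
    p <- pk_params(k_a, k_e, dose = stats::runif(1, 0.5, 5))
    times <- c(0, sort(stats::runif(5, 1, 2000)))
    ode <- deSolve::lsoda(
      y = c(orb = p$dose, iv = 0),
      times = times,
      func = function(t, y, parms)
        list(c(-k_a * y[1], k_a * y[1] - k_e * y[2])),
      parms = NULL, rtol = 1e-10, atol = 1e-12)
    closed <- solve_two_compartment(p, times, t_fd = 0)$m_iv
    expect_equal(closed, unname(ode[, "iv"]), tolerance = 1e-6)
  }
})

test_that("confluent limit is used when the rates nearly coincide", {
  k <- 0.01
  p <- pk_params(k, k * (1 + 1e-12), dose = 2)
  m <- solve_two_compartment(p, times = 100, t_fd = 0)$m_iv
  expect_equal(m, 2 * k * 100 * exp(-k * 100), tolerance = 1e-9)
})

test_that("mass bound and unimodality hold over random parameter draws", {
  set.seed(202)
  for (i in 1:25) {
    p <- pk_params(stats::runif(1, 1e-3, 0.1), stats::runif(1, 1e-5, 0.02))
    m <- solve_two_compartment(p, seq(0, 4000, by = 2), t_fd = 0)$m_iv
    expect_true(all(m >= 0) && all(m <= p$dose + 1e-12))
    sgn <- sign(diff(m))
    expect_lte(sum(diff(sgn[sgn != 0]) != 0), 1)  # one rise-fall transition
  }
})

test_that("civ_profile matches the gridded solution and vanishes before injection", {
  p <- pk_params(0.03, 0.002, dose = 1.7, v_blood = 2)
  f <- civ_profile(p, t_fd = 300)
  expect_equal(f(c(0, 100, 299.9)), c(0, 0, 0))
  tt <- c(300, 350, 700, 2000)
  expect_equal(f(tt), solve_two_compartment(p, tt, t_fd = 300)$c_iv)
})

test_that("rate recovery from a noiseless synthetic trace is within 1 percent", {
  tr <- normalized_ep_trace()
  fit <- fit_pk(tr)
  expect_lt(abs(fit$k_a - 0.02) / 0.02, 0.01)
  expect_lt(abs(fit$k_e - 0.0005) / 0.0005, 0.01)
  expect_lt(attr(fit, "residual_norm"), 1e-10)
})

test_that("fit preconditions reject traces without a resolvable peak", {
  few <- fluorescence_trace(c(310, 320, 330, 340), c(0.2, 0.5, 0.8, 1),
                            t_fd = 300, t_ep = 1030)
  expect_error(fit_pk(few), "at least 6")
  rising <- fluorescence_trace(seq(310, 400, by = 10),
                               seq(0.1, 1, length.out = 10),
                               t_fd = 300, t_ep = 1030)
  expect_error(fit_pk(rising), "past the intravascular peak")
})
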