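test_that("wall coefficient ramp evaluates piecewise as specified", {
  w <- wall_permeability(t_ep = 1030, t_del = 1090, t_sat = 1390,
                         d_sat = 0.008)
  expect_equal(dwall_at(1030, w), 0)                      # at the pulse
  expect_equal(dwall_at(1089.9, w), 0)                    # still delayed
  expect_equal(dwall_at((1090 + 1390) / 2, w), 0.004)     # ramp midpoint
  expect_equal(dwall_at(1390, w), 0.008)                  # saturation onset
  expect_equal(dwall_at(5000, w), 0.008)                  # stays saturated
  expect_error(wall_permeability(100, 50, 300, 0.01), "t_ep")
  expect_error(wall_permeability(100, 200, 200, 0.01), "exceed")
  expect_error(wall_permeability(100, 200, 300, -1), "non-negative")
})

test_that("an impermeable wall produces zero extravasation (control case)", {
  gr <- vascperm:::single_capillary_grid(20, 3.5, 1, 1)
  w <- wall_permeability(0, 50, 250, 0)
  sol <- solve_forward(gr, transport_params(10, w), function(t) rep(1, length(t)),
                       c(0, 500), out_times = c(100, 300, 500))
  expect_equal(sol$m_ev, c(0, 0, 0))
  expect_equal(sol$m_total, sol$m_iv)
})

test_that("tissue equilibrates to the boundary concentration", {
  gr <- vascperm:::single_capillary_grid(20, 3.5, 1, 1)
  w <- wall_permeability(0, 10, 60, 0.5)
  sol <- solve_forward(gr, transport_params(20, w), function(t) rep(1, length(t)),
                       c(0, 30000), out_times = 30000, max_dt = 50)
  mean_c <- sol$m_ev / gr$tissue_area
  expect_equal(mean_c, 1, tolerance = 1e-3)
  expect_true(all(abs(sol$field[gr$type == 0L] - 1) < 1e-2))
})

test_that("extravasated amount is non-decreasing while the lumen leads", {
  ds <- noiseless_ep_dataset()
  sol <- ds$forward
  expect_true(all(diff(sol$m_ev) >= -1e-10))
  expect_true(all(sol$m_ev[sol$times <= 1090] == 0))  # zero before onset
  expect_true(all(sol$m_ev >= 0))
})

test_that("sealed-domain time stepping conserves mass to round-off", {
  gr <- vascperm:::single_capillary_grid(20, 3.5, 1, 1)
  sealed_type <- gr$type
  sealed_type[sealed_type == 2L] <- 1L     # reclassify lumen as wall: sealed
  set.seed(31)
  c0 <- stats::runif(gr$nx * gr$nz)
  steps <- seq(0, 200, by = 4)
  res <- vascperm:::.adi_run_cpp(sealed_type, gr$fw_x, gr$ft_x, gr$code_x,
                                 gr$fw_z, gr$ft_z, gr$code_z, gr$h, 5,
                                 steps, rep(0.05, length(steps) - 1L),
                                 numeric(length(steps) - 1L),
                                 numeric(length(steps)), c0, FALSE)
  drift <- abs(diff(res$mass)) / res$mass[1]
  expect_lt(max(drift), 1e-10)
})

test_that("extravasation rate scales near-linearly with d_sat in the wall-limited regime", {
  # quasi-steady flux (after the wall-charging transient, well before
  # tissue backpressure) should double when the wall coefficient doubles
  gr <- vascperm:::single_capillary_grid(40, 3.5, 1, 1)
  civ1 <- function(t) rep(1, length(t))
  m_at <- function(dsat) {
    w <- wall_permeability(0, 0.001, 10, dsat)
    solve_forward(gr, transport_params(30, w), civ1, c(0, 200),
                  out_times = c(100, 200), max_dt = 5)$m_ev
  }
  m1 <- m_at(0.01); m2 <- m_at(0.02)
  expect_equal((m2[2] - m2[1]) / (m1[2] - m1[1]), 2, tolerance = 0.05)
})

test_that("model signal is normalized to its pre-pulse maximum", {
  ds <- noiseless_ep_dataset()
  sm <- signal_model(ds$forward)
  pre <- sm$times < 1030
  expect_equal(max(sm$values[pre]), 1)
  # before the permeability onset the pulsed model equals the control shape
  ctrl <- noiseless_control_dataset()
  t_pre_del <- sm$times[sm$times <= 1090]
  civ <- civ_profile(default_pk(), t_fd = 300)
  ctrl_shape <- civ(t_pre_del) / max(civ(sm$times[pre]))
  expect_equal(sm$values[sm$times <= 1090], ctrl_shape, tolerance = 1e-12)
})

test_that("pulsed and control traces agree before the permeability onset", {
  ep <- noiseless_ep_dataset()
  ctrl <- noiseless_control_dataset()
  pre_del <- ep$trace$times < 1090
  expect_equal(ep$noise_free[pre_del], ctrl$noise_free[pre_del],
               tolerance = 1e-12)
  # and diverge afterwards
  expect_gt(max(ep$noise_free - ctrl$noise_free), 0)
})
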