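test_that("identical truth and seed give bitwise-identical datasets", {
  sch <- make_schedule()
  truth <- ground_truth(default_pk(), default_wall(), noise_cv = 0.05,
                        seed = 77L)
  d1 <- simulate_trace(sch, truth)
  d2 <- simulate_trace(sch, truth)
  expect_identical(d1$trace$values, d2$trace$values)
  truth2 <- truth; truth2$seed <- 78L
  d3 <- simulate_trace(sch, truth2)
  expect_false(identical(d1$trace$values, d3$trace$values))
})

test_that("zero noise and zero background give exactly zero pre-injection samples", {
  sch <- make_schedule()
  truth <- ground_truth(default_pk(), default_wall(), background = 0,
                        noise_cv = 0)
  ds <- simulate_trace(sch, truth)
  expect_identical(ds$trace$values[ds$trace$phase == "I"],
                   rep(0, sum(ds$trace$phase == "I")))
})

test_that("a control trace decays monotonically after its post-injection peak", {
  ds <- noiseless_control_dataset()
  v <- ds$trace$values
  peak <- which.max(v)
  expect_true(all(diff(v[peak:length(v)]) <= 1e-12))
})

test_that("phase I residual CV converges to the configured noise level", {
  # long synthetic phase I: 10,000 frames of background-only signal
  iv <- data.frame(label = "A", start = 0, duration = 10000, period = 1)
  sch <- make_schedule(iv, t_fd = 10000, t_ep = 10001)
  truth <- ground_truth(default_pk(), NULL, background = 50,
                        noise_cv = 0.04, seed = 5L)
  ds <- simulate_trace(sch, truth)
  cv_emp <- stats::sd(ds$trace$values) / mean(ds$trace$values)
  expect_equal(cv_emp, 0.04, tolerance = 0.05)
})

test_that("rendered stacks carry an exact ground-truth mask", {
  sch <- make_schedule()
  truth <- ground_truth(default_pk(), default_wall(), noise_cv = 0.05,
                        seed = 9L)
  lay <- vessel_layout(width = 96, height = 72,
                       stripes = data.frame(x0 = c(20, 60), width = 12))
  st <- render_image_stack(sch, truth, lay, noise = "none", n_frames = 3)
  expect_equal(sum(st$mask), 2 * 12 * 72)
  empty <- render_image_stack(sch, truth,
                              vessel_layout(stripes = data.frame(x0 = numeric(),
                                                                 width = numeric())),
                              noise = "none", n_frames = 2)
  expect_equal(sum(empty$mask), 0)
  expect_error(vessel_layout(width = 50, stripes = data.frame(x0 = 45,
                                                              width = 12)),
               "exceed")
})

test_that("noiseless pre-injection frames are uniform background", {
  sch <- make_schedule()
  truth <- ground_truth(default_pk(), NULL, background = 80, noise_cv = 0,
                        seed = 2L)
  st <- render_image_stack(sch, truth, noise = "none", n_frames = 2)
  expect_true(st$stack$times[1] < 300)
  expect_true(all(st$stack$frames[[1]] == 80))
})
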