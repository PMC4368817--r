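test_that("objective vanishes at the generating truth and rises away from it", {
  tr <- normalized_ep_trace()
  ctx <- ep_fit_context()
  truth_theta <- c(0.008, 60, 300)
  o_truth <- objective(truth_theta, tr, ctx)
  expect_lt(o_truth, 1e-6)
  # an impermeable-wall candidate misses the post-pulse accumulation
  o_zero <- objective(c(1e-4, 60, 300), tr, ctx)
  expect_gt(o_zero, o_truth + 1)
  o_half <- objective(c(0.004, 60, 300), tr, ctx)
  expect_gt(o_half, o_truth)
})

test_that("objective is invariant to rescaling the raw trace before normalization", {
  ds <- noiseless_ep_dataset()
  ctx <- ep_fit_context()
  raw <- ds$trace
  scaled <- raw; scaled$values <- raw$values * 5
  tr1 <- normalize_trace(subtract_background(raw))
  tr5 <- normalize_trace(subtract_background(scaled))
  th <- c(0.005, 120, 200)
  expect_equal(objective(th, tr1, ctx), objective(th, tr5, ctx),
               tolerance = 1e-12)
})

test_that("the genetic search is deterministic given the seed and logs monotone progress", {
  tr <- normalized_ep_trace()
  ctx <- ep_fit_context()
  cfg <- quick_ga(seed = 3L, pop = 12L, gens = 6L, stall = 6L)
  f1 <- ga_optimize(tr, ctx, cfg)
  f2 <- ga_optimize(tr, ctx, cfg)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$objective, f2$objective)
  expect_true(all(diff(f1$log) <= 0))
  expect_true(all(f1$theta >= cfg$bounds[, 1] & f1$theta <= cfg$bounds[, 2]))
})

test_that("ga_config rejects degenerate settings", {
  expect_error(ga_config(pop_size = 3), "at least 4")
  expect_error(ga_config(bounds = rbind(c(1, 0), c(0, 1), c(0, 1))),
               "positive-width")
})

test_that("group fitting summarizes by the median over per-animal estimates", {
  # medians computed exactly as in the summary table convention
  expect_equal(stats::median(c(0.0089, 0.0086, 0.0033)), 0.0086)
  expect_equal(stats::median(c(0.0047, 0.0045, 0.0038)), 0.0045)
  tr <- normalized_ep_trace()
  ctx <- ep_fit_context()
  cfg <- quick_ga(seed = 5L, pop = 10L, gens = 3L, stall = 3L)
  grp <- fit_group(list(tr), ctx, cfg)
  expect_equal(grp$median_d_sat, grp$d_sat[1])
  expect_length(grp$failures, 0)
  expect_error(fit_group(list(), ctx, cfg), "at least one")
})
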