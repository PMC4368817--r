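make_stripe_frame <- function(width = 160, height = 120,
                              stripes = data.frame(x0 = c(30, 100),
                                                   width = 12),
                              bg = 0.2, vessel = 1, cv = 0.05, seed = 21) {
  set.seed(seed)
  truth_mask <- matrix(FALSE, width, height)
  for (j in seq_len(nrow(stripes))) {
    cols <- stripes$x0[j] + seq_len(stripes$width[j]) - 1L
    truth_mask[cols, ] <- TRUE
  }
  f <- matrix(bg, width, height)
  f[truth_mask] <- vessel
  f <- f * (1 + cv * stats::rnorm(length(f)))
  list(frame = f, mask = truth_mask)
}

test_that("vessel masking recovers bright stripes on a noisy background", {
  fx <- make_stripe_frame()
  m <- build_vessel_mask(fx$frame)
  expect_true(all(m %in% c(0, 1)))
  sens <- mean(m[fx$mask] == 1)       # true stripe pixels masked
  fpr <- mean(m[!fx$mask] == 1)       # background pixels wrongly masked
  expect_gte(sens, 0.95)
  expect_lte(fpr, 0.05)
})

test_that("a uniform frame yields an empty mask flagged as vessel-free", {
  m <- build_vessel_mask(matrix(3.7, 50, 40))
  expect_equal(sum(m), 0)
  expect_false(attr(m, "provenance")$vessels_detected)
})

test_that("raising the threshold never adds pixels to the mask", {
  fx <- make_stripe_frame()
  thresholds <- c(0.05, 0.1, 0.2, 0.4)
  sizes <- vapply(thresholds, function(th)
    sum(build_vessel_mask(fx$frame, threshold = th, cleanup = FALSE)),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("trace extraction averages unmasked pixels only", {
  frames <- list(matrix(0, 8, 6), matrix(0, 8, 6))
  frames[[2]][, ] <- 7
  st <- image_stack(frames, times = c(0, 10))
  mask <- matrix(0, 8, 6); mask[1:2, ] <- 1
  tr <- extract_trace(st, mask, t_fd = 5)
  expect_equal(tr$values, c(0, 7))
  all_masked <- matrix(1, 8, 6)
  expect_error(extract_trace(st, all_masked, t_fd = 5), "every pixel")
  expect_error(extract_trace(st, matrix(0, 4, 6), t_fd = 5), "dimensions")
})

test_that("extraction is linear in the pixel intensities", {
  set.seed(3)
  f1 <- list(matrix(stats::runif(48), 8, 6))
  f2 <- list(matrix(stats::runif(48), 8, 6))
  mask <- matrix(0, 8, 6); mask[3, 2] <- 1
  s1 <- image_stack(f1, 0); s2 <- image_stack(f2, 0)
  s12 <- image_stack(list(f1[[1]] + f2[[1]]), 0)
  expect_equal(extract_trace(s12, mask, t_fd = 5)$values,
               extract_trace(s1, mask, t_fd = 5)$values +
                 extract_trace(s2, mask, t_fd = 5)$values)
})

test_that("noiseless extraction reproduces the generator's tissue signal exactly", {
  sch <- make_schedule()
  truth <- ground_truth(default_pk(), default_wall(), background = 100,
                        noise_cv = 0, gain = 2.5, seed = 4L)
  st <- render_image_stack(sch, truth, noise = "none", n_frames = 40)
  tr <- extract_trace(st$stack, st$mask * 1, t_fd = 300, t_ep = 1030)
  expect_equal(tr$values, st$tissue_values[1:40], tolerance = 1e-12)
})

test_that("image stacks round-trip through 16-bit TIFF", {
  set.seed(8)
  frames <- lapply(1:3, function(i) matrix(stats::runif(30, 0, 400), 6, 5))
  st <- image_stack(frames, times = c(0, 20, 40))
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(st, path, scale_max = 400)
  back <- read_image_stack(path, times = st$times)
  expect_equal(length(back$frames), 3L)
  for (i in 1:3)
    expect_equal(back$frames[[i]] * 400, frames[[i]],
                 tolerance = 400 / 65535)
})
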