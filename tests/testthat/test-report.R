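test_that("permeability conversion follows P = D / thickness in cm/s", {
  expect_equal(pwall_from_dwall(0.0086, 1), 8.6e-7)
  expect_equal(pwall_from_dwall(0.0045, 1), 4.5e-7)
  expect_equal(pwall_from_dwall(0, 5), 0)
  expect_error(pwall_from_dwall(0.01, 0), "positive")
  # unit identity: with a 1 um wall, P in 1e-7 cm/s is 1000 x D in um^2/s
  d <- c(0.0089, 0.0086, 0.0033, 0.0047, 0.0045, 0.0038)
  expect_equal(pwall_from_dwall(d, 1) * 1e7, 1000 * d)
})

test_that("hydrodynamic-radius and coefficient ratios reproduce the printed comparisons", {
  expect_equal(round(stokes_einstein_ratio(26.89, 6.49), 2), 4.14)
  expect_equal(stokes_einstein_ratio(3, 3), 1)
  expect_equal(stokes_einstein_ratio(2, 1), 2)
  expect_error(stokes_einstein_ratio(-1, 2), "positive")
  expect_equal(round(coefficient_ratio(0.0086, 0.0045), 2), 1.91)
  expect_equal(round(coefficient_ratio(0.0086, 0.00183), 1), 4.7)
  expect_equal(round(coefficient_ratio(0.0045, 0.0017), 2), 2.65)
  expect_error(coefficient_ratio(1, 0), "non-zero")
})

test_that("group medians follow the even/odd sample-median convention", {
  expect_equal(stats::median(c(0.0089, 0.0086, 0.0033)), 0.0086)
  r <- permeability_report(c(0.0089, 0.0086, 0.0033), 70, 30)
  expect_equal(r$median_d_wall, 0.0086)
  expect_equal(r$median_p_wall, 8.6e-7)
  r2 <- permeability_report(c(0.0047, 0.0045, 0.0038), 2000, 5)
  expect_equal(r2$median_d_wall, 0.0045)
  even <- permeability_report(c(0.004, 0.008), 70, 30)
  expect_equal(even$median_d_wall, 0.006)   # mean of the middle pair
  single <- permeability_report(0.01, 70, 30)
  expect_equal(single$median_d_wall, 0.1 / 10)
})

test_that("post-pulse linearity diagnostic handles exact, degenerate and model traces", {
  lin <- fluorescence_trace(c(100, 1100, 1200, 1300), c(0, 1, 2, 3),
                            t_fd = 300, t_ep = 1030)
  expect_equal(postep_linearity(lin), 1)
  cst <- fluorescence_trace(c(100, 1100, 1200, 1300), c(0, 2, 2, 2),
                            t_fd = 300, t_ep = 1030)
  expect_equal(postep_linearity(cst), 0)
  short <- fluorescence_trace(c(100, 1100, 1200), c(0, 1, 2), 300, 1030)
  expect_error(postep_linearity(short), "at least 3 phase III")
  # the saturated-ramp forward model yields a near-linear post-pulse rise
  tr <- normalized_ep_trace()
  expect_gte(postep_linearity(tr), 0.95)
})

test_that("reports round-trip through JSON and enforce the conversion identity", {
  r70 <- permeability_report(c(0.0089, 0.0086, 0.0033), 70, 30,
                             radius_nm = 6.49)
  r2000 <- permeability_report(c(0.0047, 0.0045, 0.0038), 2000, 5,
                               radius_nm = 26.89)
  path <- file.path(withr::local_tempdir(), "report")
  files <- write_report(list(r70, r2000), path)
  expect_true(all(file.exists(files)))
  back <- read_report(path)
  expect_equal(back[[1]]$median_d_wall, 0.0086)
  expect_equal(back[[2]]$median_p_wall, 4.5e-7)
  expect_equal(back[[1]]$table$d_wall, r70$table$d_wall)
  tampered <- r70
  tampered$table$p_wall[1] <- 1e-3
  expect_error(write_report(tampered, file.path(withr::local_tempdir(), "x")),
               "violates")
  expect_error(write_report(list(), path), "no reports")
})

test_that("electrode metadata consistency check accepts the study protocol", {
  expect_true(check_electrode_config(1300, 6, 780))
  expect_error(check_electrode_config(1300, 6, 700), "inconsistent")
})
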