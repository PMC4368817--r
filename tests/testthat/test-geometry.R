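test_that("default geometry places four capillary layers symmetrically", {
  g <- unit_cell_geometry()
  cc <- capillary_centers(g)
  expect_equal(nrow(cc), 4L)
  expect_equal(cc$z, 72 + (0:3) * 60 * sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(cc$z, c(72, 123.96, 175.92, 227.88), tolerance = 1e-3)
  # last layer sits at depth h from the far surface, up to packing rounding
  expect_equal(cc$z[4], g$H - g$h, tolerance = 1e-2)
  expect_equal(cc$x, c(0, 30, 0, 30))
})

test_that("inconsistent geometries are rejected", {
  expect_error(unit_cell_geometry(r = 20, a = 42), "fit inside")
  expect_error(unit_cell_geometry(h = 160), "exceed 2")
  expect_error(unit_cell_geometry(h = 40), "inconsistent packing")
})

test_that("rasterized lumen area approaches the analytic cross-section", {
  g <- unit_cell_geometry()
  gr <- build_grid(g, 0.5)
  # four half cross-sections on the symmetry walls = 2 full capillaries
  analytic <- 2 * pi * g$r^2
  expect_lt(abs(gr$lumen_area - analytic) / analytic, 0.05)
  expect_equal(gr$lumen_area + gr$wall_area + gr$tissue_area,
               (g$a / 2) * g$H)
})

test_that("unresolved wall resolutions are rejected", {
  expect_error(build_grid(unit_cell_geometry(), 2), "unresolved")
})

test_that("face material fractions are exact on a known configuration", {
  # single capillary r = 3.5, w = 1 centered at (10, 10): the segment from
  # (10.5 - 1, 13.5) to (10.5, 13.5)... use a radial face directly below the
  # center: cells (10.5, 5.5) -> (10.5, 6.5), distances 4.53 to 3.54: the
  # r + w = 4.5 circle crosses it
  gr <- vascperm:::single_capillary_grid(20, 3.5, 1, 1)
  f <- vascperm:::.face_fractions(10.5, 5.5, 10.5, 6.5,
                                  data.frame(x = 10, z = 10), 3.5, 1)
  # analytic crossing of dist = 4.5: z with sqrt(0.25 + (z-10)^2) = 4.5
  z_cross <- 10 - sqrt(4.5^2 - 0.25)
  expect_equal(f$fw, (6.5 - z_cross) / 1, tolerance = 1e-10)
  expect_equal(f$ft, (z_cross - 5.5) / 1, tolerance = 1e-10)
  expect_equal(f$fl, 0)
  # fractions always partition the segment
  expect_true(all(abs(gr$fw_x + gr$ft_x - 1) <= 1 + 1e-12))
})
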