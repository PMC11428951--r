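test_that("optical properties derive the diffusion coefficient", {
  op <- optical_properties(0.02, 10)
  expect_equal(op$D, 1 / (3 * 10.02))
  expect_error(optical_properties(-1, 10), "positive")
  expect_error(optical_properties(0.02, 10, kappa = 0), "positive")
})

test_that("phantom constructor validates dimensions", {
  ph <- cylinder_phantom(3.0, 2.3, fx_optics())
  expect_equal(ph$radius_cm, 1.5)
  ph2 <- cylinder_phantom(4.0, 4.0, fx_optics())
  expect_equal(ph2$height_cm, 4.0)
  expect_error(cylinder_phantom(0, 2.3, fx_optics()), "positive")
})

test_that("edge-to-edge distance is the in-plane surface gap", {
  a <- xlct_target(c(-3, 0, 0), diameter_mm = 4)
  b <- xlct_target(c(3, 0, 0), diameter_mm = 4)
  expect_equal(compute_eed(a, b), 2)
  # 5 mm centre distance, 3 and 4 mm diameters -> 1.5 mm
  c1 <- xlct_target(c(0, 0, 0), diameter_mm = 3)
  c2 <- xlct_target(c(0, 5, 0), diameter_mm = 4)
  expect_equal(compute_eed(c1, c2), 1.5)
  # identical centres overlap (negative)
  expect_lt(compute_eed(a, a), 0)
  # symmetry
  expect_equal(compute_eed(a, b), compute_eed(b, a))
})

test_that("target placement respects all constraints and is reproducible", {
  ph <- fx_phantom()
  tgs <- sample_targets(ph, 2, center_range_mm = 10,
                        eed_range_mm = c(0.3, 2.5), seed = 1)
  expect_length(tgs, 2)
  ee <- compute_eed(tgs[[1]], tgs[[2]])
  expect_gte(ee, 0.3); expect_lte(ee, 2.5)
  for (tg in tgs) {
    expect_true(all(abs(tg$center_mm[1:2]) <= 10))
    expect_lt(sqrt(sum(tg$center_mm[1:2]^2)) + tg$radius_mm, 15)
  }
  tgs2 <- sample_targets(ph, 2, seed = 1)
  expect_identical(tgs, tgs2)

  # mouse-mode centre range
  tgs3 <- sample_targets(ph, 3, center_range_mm = 8, seed = 4)
  for (tg in tgs3) expect_true(all(abs(tg$center_mm[1:2]) <= 8))
  prs <- utils::combn(3, 2)
  for (k in seq_len(ncol(prs))) {
    e <- compute_eed(tgs3[[prs[1, k]]], tgs3[[prs[2, k]]])
    expect_gte(e, 0.3); expect_lte(e, 2.5)
  }

  expect_error(sample_targets(ph, 2, eed_range_mm = c(-1, 0)), "interval")
  expect_error(sample_targets(ph, 2, eed_range_mm = c(0.3, 0.300001),
                              max_attempts = 5),
               "budget")
})

test_that("rasterization fills voxel centres inside targets", {
  grid <- voxel_grid(30, 30, 7, diameter_mm = 30, z_spacing_mm = 1)
  # empty target list
  ras0 <- rasterize_targets(list(), grid)
  expect_true(all(ras0$truth == 0))
  expect_false(any(ras0$roi_mask))

  # single 4 mm x 4 mm target on a 1 mm grid: about pi * 2^2 * 4 ~ 50 voxels
  tg <- xlct_target(c(0, 0, 0), diameter_mm = 4, height_mm = 4,
                    concentration = 50)
  ras <- rasterize_targets(list(tg), grid)
  n_in <- sum(ras$truth > 0)
  expect_gte(n_in, 50 * 0.8)
  expect_lte(n_in, 50 * 1.2)
  expect_true(all(ras$truth[ras$truth > 0] == 50))
  # ROI mask covers the support
  expect_true(all(ras$roi_mask[ras$truth > 0]))
  # determinism and non-negativity
  expect_identical(ras, rasterize_targets(list(tg), grid))
  expect_true(all(ras$truth >= 0))
})

test_that("voxel grid geometry matches the full-scale configuration", {
  g <- voxel_grid(128, 128, 7, diameter_mm = 30, z_spacing_mm = 1)
  expect_equal(g$dx_mm, 30 / 128)
  expect_equal(g$z_mm, seq(-3, 3, by = 1))
  expect_equal(length(g$x_mm), 128)
})
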