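test_that("weight matrix entries are finite and non-negative", {
  fx <- fx_forward()
  expect_true(all(is.finite(fx$wm$W)))
  expect_gte(min(fx$wm$W), 0)
})

test_that("adjoint and direct assemblies agree entrywise", {
  fx <- fx_forward()
  wm_d <- build_weight_matrix(fx$mesh, fx$grid, fx$detector, fx$source,
                              method = "direct", system = fx$system)
  expect_lt(max(abs(fx$wm$W - wm_d$W)) / max(wm_d$W), 1e-6)
})

test_that("W x reproduces the direct forward simulation", {
  fx <- fx_forward()
  for (i in 1:5) {
    tg <- sample_targets(fx$phantom, 2, seed = i)
    ras <- rasterize_targets(tg, fx$grid)
    p_lin <- project_volume(fx$wm, ras$truth)
    p_sim <- simulate_projections(fx$phantom, tg, fx$detector, fx$source,
                                  mesh = fx$mesh, grid = fx$grid,
                                  system = fx$system)
    expect_lt(sqrt(sum((p_lin$images - p_sim$images)^2)) /
                sqrt(sum(p_sim$images^2)), 1e-6)
  }
})

test_that("the forward chain is linear in the concentration field", {
  fx <- fx_forward()
  set.seed(31)
  n1 <- runif(ncol(fx$wm$W)); n2 <- runif(ncol(fx$wm$W))
  pa <- project_volume(fx$wm, 2 * n1 + 3 * n2)$images
  pb <- 2 * project_volume(fx$wm, n1)$images +
    3 * project_volume(fx$wm, n2)$images
  expect_equal(pa, pb, tolerance = 1e-12)
})

test_that("voxels with zero X-ray excitation have identically zero columns", {
  fx <- fx_forward()
  # attenuation so extreme that deep voxels see an (exactly underflowed)
  # zero beam while rim voxels still receive some excitation
  ph_dark <- cylinder_phantom(3.0, 2.3, fx_optics(), xray_mu_t = 2000)
  mesh <- mesh_cylinder(ph_dark, 0.4)
  wm <- build_weight_matrix(mesh, fx$grid, fx$detector, fx$source)
  g <- wm$grid
  i0 <- wm$voxel_idx - 1L
  cx <- g$x_mm[(i0 %% g$nx) + 1L]
  cy <- g$y_mm[((i0 %/% g$nx) %% g$ny) + 1L]
  deep <- sqrt(cx^2 + cy^2) < 5
  expect_gt(sum(deep), 0)
  expect_true(all(wm$W[, deep] == 0))
  expect_gt(max(wm$W), 0)
})

test_that("measurement stacking order matches the operator rows", {
  fx <- fx_forward()
  set.seed(12)
  x <- runif(ncol(fx$wm$W))
  ps <- project_volume(fx$wm, x)
  y <- cbxlct:::stack_measurements(ps)
  expect_equal(y, as.vector(fx$wm$W %*% x))
})
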