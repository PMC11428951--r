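test_that("boundary projection is periodic in the view angle", {
  fx <- fx_forward()
  set.seed(2)
  phi <- runif(nrow(fx$mesh$nodes))
  img0 <- boundary_projection(phi, fx$mesh, 0, fx$detector)
  img360 <- boundary_projection(phi, fx$mesh, 360, fx$detector)
  expect_identical(img0, img360)
})

test_that("a centred target yields a left-right symmetric image", {
  ph <- fx_phantom()
  # the consistent Galerkin scheme converges to the symmetric solution;
  # a fine mesh keeps the residual mesh-diagonal imprint below 2%
  mesh <- mesh_cylinder(ph, 0.12)
  sys <- assemble_diffusion_system(mesh, ph$optics, scheme = "galerkin")
  grid <- voxel_grid(24, 24, 3, diameter_mm = 30)
  det <- detector_model(24, 24, extent_cm = 3.2, angles_deg = 0)
  tg <- list(xlct_target(c(0, 0, 0), diameter_mm = 6, height_mm = 6))
  proj <- simulate_projections(ph, tg, det, xray_source(), mesh = mesh,
                               grid = grid, system = sys)
  img <- proj$images[1, , ]
  flipped <- img[rev(seq_len(nrow(img))), ]
  expect_lt(sqrt(sum((img - flipped)^2)) / sqrt(sum(img^2)), 0.02)
})

test_that("the default detector produces 24 images of 128 x 128", {
  ph <- fx_phantom()
  mesh <- mesh_cylinder(ph, 0.5)
  det <- detector_model()  # 128 x 128, 24 views at 15 degrees
  tg <- list(xlct_target(c(3, 0, 0), diameter_mm = 4))
  proj <- simulate_projections(ph, tg, det, xray_source(), mesh = mesh,
                               grid = voxel_grid(24, 24, 3, diameter_mm = 30))
  expect_equal(dim(proj$images), c(24, 128, 128))
})

test_that("projections are linear in concentration and vanish without targets", {
  fx <- fx_forward()
  p0 <- simulate_projections(fx$phantom, list(), fx$detector, fx$source,
                             mesh = fx$mesh, grid = fx$grid,
                             system = fx$system)
  expect_true(all(p0$images == 0))
  tg <- list(xlct_target(c(3, 2, 0), diameter_mm = 4, concentration = 50))
  tg2 <- list(xlct_target(c(3, 2, 0), diameter_mm = 4, concentration = 100))
  p1 <- simulate_projections(fx$phantom, tg, fx$detector, fx$source,
                             mesh = fx$mesh, grid = fx$grid,
                             system = fx$system)
  p2 <- simulate_projections(fx$phantom, tg2, fx$detector, fx$source,
                             mesh = fx$mesh, grid = fx$grid,
                             system = fx$system)
  expect_equal(p2$images, 2 * p1$images, tolerance = 1e-12)
})

test_that("measurement noise realizes the requested SNR", {
  fx <- fx_forward()
  tg <- list(xlct_target(c(2, -2, 0), diameter_mm = 4))
  proj <- simulate_projections(fx$phantom, tg, fx$detector, fx$source,
                               mesh = fx$mesh, grid = fx$grid,
                               system = fx$system)
  expect_identical(add_gaussian_noise(proj, Inf), proj)
  for (snr in c(30, 25, 20, 15)) {
    noisy <- add_gaussian_noise(proj, snr, seed = 42)
    realized <- 10 * log10(mean(proj$images^2) /
                             mean((noisy$images - proj$images)^2))
    expect_lt(abs(realized - snr), 0.5)
  }
  n1 <- add_gaussian_noise(proj, 20, seed = 9)
  n2 <- add_gaussian_noise(proj, 20, seed = 9)
  expect_identical(n1, n2)
})

test_that("projection stacks round-trip through multi-page TIFF", {
  fx <- fx_forward()
  set.seed(8)
  imgs <- array(runif(4 * 20 * 20), c(4, 20, 20))
  ps <- projection_set(imgs, fx$detector$angles_deg)
  path <- tempfile(fileext = ".tif")
  write_projections_tiff(ps, path)
  back <- read_projections_tiff(path)
  expect_equal(back$images, ps$images, tolerance = 1e-6)
  expect_equal(back$angles_deg, ps$angles_deg)
  unlink(c(path, paste0(path, ".angles.json")))
})
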