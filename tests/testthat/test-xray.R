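test_that("Lambert-Beer attenuation matches closed forms", {
  op <- fx_optics()
  # zero attenuation: intensity equals the source everywhere
  ph0 <- cylinder_phantom(3.0, 2.3, op, xray_mu_t = 0)
  src <- xray_source(distance_cm = 20, intensity = 2.5)
  pts <- rbind(c(0, 0, 0), c(1, 0.5, -0.3), c(-1.2, 0, 0.8))
  expect_equal(xray_intensity_field(src, ph0, pts), rep(2.5, 3))

  # homogeneous mu_t: path length through the cylinder to the centre is the
  # radius, so X(centre) = X0 * exp(-mu_t * R)
  ph <- cylinder_phantom(3.0, 2.3, op, xray_mu_t = 0.2)
  xc <- xray_intensity_field(xray_source(intensity = 1), ph,
                             matrix(c(0, 0, 0), 1))
  expect_equal(xc, exp(-0.2 * 1.5), tolerance = 1e-12)

  # a point 1 cm past the entry along the source axis attenuates by e^-0.2
  # relative: monotone decrease with depth along the ray
  depths <- seq(-1.4, 1.4, length.out = 15)  # along x towards the source
  pts2 <- cbind(depths, 0, 0)
  xs <- xray_intensity_field(xray_source(), ph, pts2, angle_deg = 0)
  # source sits at -x for view 0; intensity decreases with increasing x
  expect_true(all(diff(xs) < 0))
  # ratio over a 1 cm step deep inside equals exp(-mu_t * 1)
  i1 <- which.min(abs(depths - (-0.5))); i2 <- which.min(abs(depths - 0.5))
  expect_equal(xs[i2] / xs[i1], exp(-0.2 * (depths[i2] - depths[i1])),
               tolerance = 1e-9)
})

test_that("points outside the phantom are rejected", {
  ph <- fx_phantom()
  expect_error(xray_intensity_field(xray_source(), ph,
                                    matrix(c(2, 0, 0), 1)),
               "inside")
})

test_that("detector model validates its view angles", {
  expect_error(detector_model(angles_deg = c(0, 0)), "strictly increasing")
  expect_error(detector_model(angles_deg = c(10, 370)), "strictly increasing")
  d <- detector_model(64, 64, 3.2, seq(0, 345, 15))
  expect_equal(d$n_views, 24)
})
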