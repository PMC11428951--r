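test_that("local SSIM matches closed forms on constant patches", {
  p <- ssim_params()
  a <- matrix(0.4, 11, 11)
  expect_equal(local_ssim(a, a, p), 1)
  set.seed(1)
  r1 <- matrix(runif(121), 11, 11); r2 <- matrix(runif(121), 11, 11)
  expect_equal(local_ssim(r1, r2, p), local_ssim(r2, r1, p))
  # constant patches 1 vs 0: (C1 / (1 + C1)) * 1
  one <- matrix(1, 11, 11); zero <- matrix(0, 11, 11)
  expect_equal(local_ssim(one, zero, p), p$C1 / (1 + p$C1))
})

test_that("MSSIM is 1 for identical volumes and bounded for random pairs", {
  p <- ssim_params(window_size = 7)
  set.seed(2)
  x <- array(runif(10 * 10 * 2), c(10, 10, 2))
  expect_equal(mssim(x, x, p), 1)
  for (i in 1:200) {
    a <- array(runif(9 * 9), c(9, 9, 1))
    b <- array(runif(9 * 9), c(9, 9, 1))
    v <- mssim(a, b, p)
    expect_gte(v, -1); expect_lte(v, 1)
  }
})

test_that("MSSIM equals the hand-averaged windowed SSIM", {
  p <- ssim_params()
  set.seed(3)
  # 12 columns give exactly two 11 x 11 window positions per slice
  a <- matrix(runif(11 * 12), 11, 12)
  b <- matrix(runif(11 * 12), 11, 12)
  by_hand <- mean(c(local_ssim(a[, 1:11], b[, 1:11], p),
                    local_ssim(a[, 2:12], b[, 2:12], p)))
  expect_equal(mssim(a, b, p), by_hand, tolerance = 1e-12)
})

test_that("SSIM loss complements MSSIM and exceeds 1 when anti-correlated", {
  p <- ssim_params(window_size = 7)
  set.seed(4)
  x <- array(runif(12 * 12), c(12, 12, 1))
  expect_equal(ssim_loss(x, x, p), 0)
  y <- array(runif(12 * 12), c(12, 12, 1))
  expect_equal(ssim_loss(x, y, p), 1 - mssim(x, y, p))
  anti <- max(x) - x  # negative covariance in every window
  expect_gt(ssim_loss(x, anti, p), 1)
})

test_that("MSE loss is the mean squared difference", {
  set.seed(5)
  a <- array(runif(40), c(4, 5, 2))
  expect_equal(mse_loss(a, a), 0)
  expect_equal(mse_loss(a + 1, a), 1)
  d <- array(runif(40), c(4, 5, 2))
  expect_equal(mse_loss(a + 2 * d, a), 4 * mse_loss(a + d, a))
})

test_that("composite loss decomposes and recombines per definition", {
  p <- ssim_params(window_size = 7)
  set.seed(6)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  y <- array(runif(16 * 16 * 3), c(16, 16, 3))
  roi <- array(FALSE, c(16, 16, 3)); roi[5:10, 6:11, 2] <- TRUE
  expect_equal(composite_loss(x, x, roi, p)$total, 0)
  lc <- composite_loss(x, y, roi, p)
  expect_equal(lc$total,
               lc$mse_full + lc$mse_roi +
                 2 * (lc$ssim_loss_full + lc$ssim_loss_roi))
  expect_error(composite_loss(x, y, array(FALSE, c(16, 16, 3)), p), "ROI")
})

test_that("analytic composite-loss gradient matches finite differences", {
  p <- ssim_params(window_size = 7)
  set.seed(42)
  xr <- array(runif(8 * 8 * 3), c(8, 8, 3))
  xt <- array(runif(8 * 8 * 3), c(8, 8, 3))
  roi <- array(FALSE, c(8, 8, 3)); roi[3:6, 2:5, 2] <- TRUE
  g <- composite_loss(xr, xt, roi, p, want_grad = TRUE)$grad
  eps <- 1e-6
  idx <- seq(1, length(xr), by = 7)
  for (i in idx) {
    xp <- xr; xp[i] <- xp[i] + eps
    xm <- xr; xm[i] <- xm[i] - eps
    fd <- (composite_loss(xp, xt, roi, p)$total -
             composite_loss(xm, xt, roi, p)$total) / (2 * eps)
    expect_lt(abs(g[i] - fd) / max(abs(fd), 1e-8), 1e-4)
  }
})
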