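test_that("max-normalization rescales, warns on zero, and is idempotent", {
  v <- array(c(1, 2, 4), c(3, 1, 1))
  nv <- normalize_volume(v)
  expect_equal(max(nv), 1)
  expect_equal(as.vector(nv), c(0.25, 0.5, 1))
  expect_warning(z <- normalize_volume(array(0, c(2, 2, 1))), "all-zero")
  expect_true(all(z == 0))
  expect_identical(normalize_volume(nv), nv)
})

test_that("Dice matches the counting definition", {
  # |A| = 120, |B| = 100, overlap 80 -> 160/220
  a <- c(rep(TRUE, 80), rep(TRUE, 40), rep(FALSE, 100))
  b <- c(rep(TRUE, 80), rep(FALSE, 40), rep(TRUE, 20), rep(FALSE, 80))
  expect_equal(dice(a, b), 160 / 220)
  expect_equal(dice(a, b), dice(b, a))
  # identical and disjoint masks
  expect_equal(dice(a, a), 1)
  expect_equal(dice(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_message(d0 <- dice(c(FALSE, FALSE), c(FALSE, FALSE)), "empty")
  expect_equal(d0, 1)
  # relative thresholding makes Dice invariant to monotone rescaling
  set.seed(1)
  v <- array(runif(125), c(5, 5, 5))
  t <- v > 0.7
  expect_equal(dice(v, t), dice(5 * v + 0, t))
  expect_equal(dice(v, t), dice(v^3, t, threshold_frac = 0.5^3))
})

test_that("CNR matches its weighted-variance definition", {
  # mu 1 vs 0 with equal variances 0.01: weights cancel, CNR = 10
  roi <- c(TRUE, TRUE, FALSE, FALSE)
  bck <- c(FALSE, FALSE, TRUE, TRUE)
  v <- c(1.1, 0.9, 0.1, -0.1)
  expect_equal(cnr(v, roi, bck), 1 / sqrt(0.01))
  # scale invariance; shift invariance
  expect_equal(cnr(3 * v, roi, bck), cnr(v, roi, bck))
  expect_equal(cnr(v + 5, roi, bck), cnr(v, roi, bck))
  # equal means give zero
  expect_equal(cnr(c(1, 3, 1, 3), roi, bck), 0)
  expect_warning(ci <- cnr(c(1, 1, 0, 0), roi, bck), "infinite")
  expect_equal(ci, Inf)
  expect_error(cnr(v, roi, roi), "disjoint")
})

test_that("line profiles sample the normalized volume trilinearly", {
  v <- array(2, c(6, 6, 3))
  pr <- intensity_profile(v, c(1, 1, 1), c(6, 6, 3), n_samples = 10)
  expect_equal(pr$intensity, rep(1, 10), tolerance = 1e-12)
  # two well-separated peaks produce two local maxima along the line
  v2 <- array(0, c(21, 5, 3))
  v2[6, 3, 2] <- 1; v2[16, 3, 2] <- 1
  pr2 <- intensity_profile(v2, c(1, 3, 2), c(21, 3, 2), n_samples = 41)
  y <- pr2$intensity
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  expect_equal(length(peaks), 2)
  # endpoints are returned exactly
  pr3 <- intensity_profile(v2, c(6, 3, 2), c(16, 3, 2), n_samples = 2)
  expect_equal(pr3$intensity, c(1, 1))
  expect_error(intensity_profile(v2, c(0, 1, 1), c(2, 2, 2)), "inside")
})

test_that("connected components resolve separated blobs", {
  m <- array(FALSE, c(10, 10, 3))
  m[2:3, 2:3, 1:2] <- TRUE
  m[7:8, 7:8, 2:3] <- TRUE
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(sum(lab > 0), sum(m))
  # diagonal touching is not 6-connected
  m2 <- array(FALSE, c(4, 4, 1))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 1] <- TRUE
  expect_equal(max(label_components(m2)), 2)
  v <- array(0, c(10, 10, 3))
  v[2:3, 2:3, 2] <- 1; v[7:8, 7:8, 2] <- 0.8
  expect_equal(count_components(v, 0.5), 2L)
  expect_equal(count_components(v, 0.9), 1L)
})

test_that("run_experiment validates its method list", {
  fx <- fx_forward()
  expect_error(run_experiment(list(type = "resolution"), character(0),
                              fx$wm),
               "non-empty")
  expect_error(run_experiment(list(type = "resolution"), "unknown", fx$wm),
               "non-empty|subset")
})
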