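fx_spec <- function() {
  fx <- fx_forward()
  sample_spec(fx$phantom, fx$grid, fx$detector, fx$source, n_targets = 2,
              input_shape = c(24, 24))
}

test_that("sample generation is bit-reproducible and shaped correctly", {
  fx <- fx_forward()
  spec <- fx_spec()
  s1 <- generate_sample(spec, seed = 5, wm = fx$wm)
  s2 <- generate_sample(spec, seed = 5, wm = fx$wm)
  expect_identical(s1, s2)
  expect_equal(dim(s1$projections), c(4, 24, 24))
  expect_equal(dim(s1$truth), c(20, 20, 3))
  expect_true(all(s1$truth >= 0))

  # zero concentration: zero projections and truth
  spec0 <- fx_spec(); spec0$concentration <- 0
  s0 <- generate_sample(spec0, seed = 5, wm = fx$wm)
  expect_true(all(s0$projections == 0))
  expect_true(all(s0$truth == 0))
})

test_that("datasets regenerate bit-exactly from the manifest", {
  fx <- fx_forward()
  spec <- fx_spec()
  dir1 <- tempfile(); dir2 <- tempfile()
  man1 <- generate_dataset(spec, 6, c(train = 0.5, val = 0.5),
                           master_seed = 3, out_dir = dir1, wm = fx$wm)
  man2 <- generate_dataset(spec, 6, c(train = 0.5, val = 0.5),
                           master_seed = 3, out_dir = dir2, wm = fx$wm)
  expect_equal(man1$seeds, man2$seeds)
  expect_equal(man1$config_hash, man2$config_hash)
  for (i in seq_along(man1$paths)) {
    expect_identical(readRDS(man1$paths[i]), readRDS(man2$paths[i]))
  }
  # split accounting
  expect_equal(sum(man1$split == "train"), 3)
  expect_equal(sum(man1$split == "val"), 3)
  expect_error(generate_dataset(spec, 0, master_seed = 1, out_dir = dir1),
               ">= 1")
  expect_error(generate_dataset(spec, 4, c(a = 0.6, b = 0.6),
                                master_seed = 1, out_dir = dir1),
               "sum to 1")
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("load-time normalization scales projections and truth", {
  fx <- fx_forward()
  s <- generate_sample(fx_spec(), seed = 2, wm = fx$wm)
  ns <- load_sample(s, normalize = TRUE, concentration = 50)
  expect_equal(max(ns$projections), 1)
  expect_true(all(ns$truth %in% c(0, 1)))
})

test_that("area-weighted resize preserves constants, means and the identity", {
  img <- matrix(runif(128 * 128), 128, 128)
  expect_equal(resize_projection(img, c(128, 128)), img)
  cst <- matrix(3.7, 50, 40)
  out <- resize_projection(cst, c(17, 13))
  expect_equal(as.vector(out), rep(3.7, 17 * 13))
  # smooth image downsized 256 -> 128 keeps its mean within 1%
  g <- outer(seq(0, 1, length.out = 256), seq(0, 1, length.out = 256),
             function(a, b) exp(-((a - 0.4)^2 + (b - 0.6)^2) / 0.05))
  down <- resize_projection(g, c(128, 128))
  expect_lt(abs(mean(down) - mean(g)) / mean(g), 0.01)
  expect_gte(min(down), 0)
})

test_that("two-target randomization covers the prescribed ranges", {
  ph <- fx_phantom()
  set.seed(100)
  draws <- lapply(derive_seeds_exposed(100, 500), function(s) {
    sample_targets(ph, 2, seed = s)
  })
  eeds <- vapply(draws, function(t) compute_eed(t[[1]], t[[2]]), numeric(1))
  # first-target coordinates are one independent draw per configuration
  xs <- vapply(draws, function(t) t[[1]]$center_mm[1], numeric(1))
  ys <- vapply(draws, function(t) t[[1]]$center_mm[2], numeric(1))
  expect_lt(min(eeds), 0.5); expect_gt(max(eeds), 2.3)
  expect_lt(min(xs), -9); expect_gt(max(xs), 9)
  # centres are close to uniform over the sampling square
  expect_gt(stats::ks.test(xs, "punif", -10, 10)$p.value, 0.01)
  expect_gt(stats::ks.test(ys, "punif", -10, 10)$p.value, 0.01)
})
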