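test_that("configured shapes chain through encoder and decoder", {
  scaled <- net_config_scaled()
  expect_equal(scaled$enc_shapes[[6]], c(3L, 3L, 3L))
  expect_equal(scaled$dec_shapes[[6]], c(5L, 48L, 48L))
  full <- net_config_full()
  expect_equal(full$input_shape, c(24L, 128L, 128L))
  expect_equal(full$output_shape, c(7L, 128L, 128L))
  expect_equal(full$enc_shapes[[6]], c(3L, 4L, 4L))
  expect_equal(full$dec_shapes[[1]], c(7L, 4L, 4L))
  expect_error(net_config_scaled(input_shape = c(13, 48, 48)), "divisible")
})

test_that("the network maps input to output shape with non-negative values", {
  cfg <- fx_tiny_net()
  net <- build_network(cfg, seed = 1)
  x <- array(runif(4 * 8 * 8 * 2), c(4, 8, 8, 1, 2))
  y <- cbxlct:::network_forward(net, x, training = FALSE)$y
  expect_equal(dim(y), c(3, 8, 8, 1, 2))
  expect_gte(min(y), 0)
  # evaluation mode is deterministic
  y2 <- cbxlct:::network_forward(net, x, training = FALSE)$y
  expect_identical(y, y2)
})

test_that("skip and attention toggles add parameters monotonically", {
  n_full <- count_parameters(build_network(fx_tiny_net(), 1))
  n_noskip <- count_parameters(build_network(fx_tiny_net(skip = FALSE), 1))
  n_noatt <- count_parameters(build_network(fx_tiny_net(dual_sampling = FALSE), 1))
  n_none <- count_parameters(build_network(
    fx_tiny_net(skip = FALSE, dual_sampling = FALSE), 1))
  expect_gt(n_full, n_noskip)
  expect_gt(n_full, n_noatt)
  expect_lt(n_none, n_noskip)
  expect_lt(n_none, n_noatt)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- fx_tiny_net()
  net <- build_network(cfg, seed = 3)
  set.seed(9)
  x <- array(runif(4 * 8 * 8 * 2), c(4, 8, 8, 1, 2))
  fw <- cbxlct:::network_forward(net, x, training = TRUE)
  R <- array(rnorm(length(fw$y)), dim(fw$y))
  for (e in net$envs) cbxlct:::zero_grads(e)
  gx <- cbxlct:::network_backward(net, fw$cache, R)
  loss_of <- function() {
    sum(cbxlct:::network_forward(net, x, training = TRUE)$y * R)
  }
  snap <- cbxlct:::snapshot_params(net)
  eps <- 1e-6
  checks <- list(c("enc1", "w", 5), c("enc3", "gamma", 2), c("fc1", "w", 17),
                 c("dec2", "w", 11), c("dec4", "w1", 2), c("out", "w", 1))
  for (spec in checks) {
    env <- net$envs[[spec[1]]]; nm <- spec[2]; i <- as.integer(spec[3])
    v <- get(nm, envir = env)
    v2 <- v; v2[i] <- v2[i] + eps; assign(nm, v2, envir = env)
    lp <- loss_of(); cbxlct:::restore_params(net, snap)
    v2 <- v; v2[i] <- v2[i] - eps; assign(nm, v2, envir = env)
    lm <- loss_of(); cbxlct:::restore_params(net, snap)
    fd <- (lp - lm) / (2 * eps)
    g <- get(paste0("g_", nm), envir = env)
    expect_lt(abs(g[i] - fd) / max(abs(fd), 1e-8), 1e-4)
  }
  # input gradient
  i <- 57
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  fd <- (sum(cbxlct:::network_forward(net, xp, TRUE)$y * R) -
           sum(cbxlct:::network_forward(net, xm, TRUE)$y * R)) / (2 * eps)
  expect_lt(abs(gx[i] - fd) / max(abs(fd), 1e-8), 1e-4)
})

test_that("a tiny model overfits ten samples", {
  # smooth-blob recovery at miniature scale: a few hundred optimization
  # steps contract the training loss by an order of magnitude (the
  # SSIM-bearing objective has a structural floor, so an exact-fit loss
  # near zero is not reachable through a strided decoder)
  set.seed(21)
  g1 <- function(n, c0, s) exp(-((seq_len(n) - c0)^2) / (2 * s^2))
  samples <- lapply(1:10, function(i) {
    cx <- runif(1, 3, 6); cy <- runif(1, 3, 6)
    blob <- outer(g1(8, cx, 1.2), g1(8, cy, 1.2))
    truth <- array(0, c(8, 8, 3))
    for (k in 1:3) truth[, , k] <- blob * c(0.5, 1, 0.5)[k]
    proj <- array(0, c(4, 8, 8))
    for (v in 1:4) proj[v, , ] <- blob * runif(1, 0.8, 1.2)
    structure(list(projections = proj, truth = truth,
                   roi_mask = array(TRUE, c(8, 8, 3)), seed = i),
              class = "training_sample")
  })
  cfg <- net_config(input_shape = c(4, 8, 8), output_shape = c(3, 8, 8),
                    enc_channels = c(8, 16, 16, 16, 16),
                    enc_pools = list(c(2, 2, 2), c(2, 2, 2), c(1, 1, 1),
                                     c(1, 2, 2), c(1, 1, 1)),
                    bottleneck = 64,
                    dec_channels = c(16, 16, 8, 8, 8),
                    dec_strides = list(c(1, 2, 2), c(1, 2, 2), c(1, 2, 2),
                                       c(1, 1, 1), c(1, 1, 1)),
                    dec_start_channels = 16, dual_sampling = FALSE,
                    output_activation = "softplus", out_bias_init = -1)
  tc <- train_config(batch_size = 5, epochs = 100, lr = 1e-2, seed = 1)
  m <- train_model(samples, samples, cfg,
                   tc, ssim = ssim_params(window_size = 7))
  h <- m$history
  expect_lt(h$train_total[nrow(h)], 0.1 * h$train_total[1])
})

test_that("the learning rate halves after a validation plateau", {
  tc <- train_config(batch_size = 64, epochs = 200, lr = 2e-5,
                     lr_factor = 0.5, patience = 5)
  expect_equal(tc$lr * tc$lr_factor, 1e-5)
  expect_equal(tc$batch_size, 64L)
  expect_equal(tc$epochs, 200L)
})

test_that("models survive a save/load round trip with identical inference", {
  cfg <- fx_tiny_net()
  set.seed(33)
  samples <- lapply(1:4, function(i) {
    structure(list(projections = array(runif(4 * 8 * 8), c(4, 8, 8)),
                   truth = array(runif(8 * 8 * 3), c(8, 8, 3)),
                   roi_mask = array(TRUE, c(8, 8, 3)), seed = i),
              class = "training_sample")
  })
  m <- train_model(samples[1:3], samples[4], cfg,
                   train_config(batch_size = 2, epochs = 2, lr = 1e-3),
                   ssim = ssim_params(window_size = 7))
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  p1 <- predict_volume(m, samples[[4]]$projections)
  p2 <- predict_volume(m2, samples[[4]]$projections)
  expect_identical(p1, p2)
  unlink(path)
})

test_that("the four ablation configurations build without code edits", {
  abl <- ablation_configs(fx_tiny_net())
  expect_named(abl, c("none", "no_skip", "no_roi", "full"))
  for (a in abl) {
    net <- build_network(a$net_config, seed = 1)
    expect_s3_class(net, "xlct_network")
  }
  expect_false(abl$none$net_config$skip)
  expect_false(abl$none$use_roi_loss)
  expect_true(abl$full$net_config$skip)
})
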