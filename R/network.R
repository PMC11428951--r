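# The 3D encoder-decoder reconstruction network: five convolutional encoder
# blocks (conv 3x3x3 -> batch norm -> LeakyReLU -> max pool), two fully
# connected bottleneck layers, and five transposed-convolution decoder
# blocks (tconv -> batch norm -> ReLU -> dual-sampling channel attention),
# with nearest-resized encoder skip connections concatenated at each decoder
# stage and a non-negative (softplus) 1x1x1 output head. The stacked multi-view
# projections form the depth axis of a single-channel 3D input volume; the
# output is the z-stack of reconstructed slices.

#' Network architecture configuration
#'
#' Validates and derives every shape of the encoder-decoder. The full-scale
#' configuration maps a (24, 128, 128) projection stack to a (7, 128, 128)
#' volume; the scaled-down configuration maps (12, 48, 48) to (5, 48, 48).
#' Ablation variants (no skip connections, no dual-sampling attention) are
#' pure configuration toggles.
#'
#' @param input_shape Length-3: (views, height, width) of the input stack.
#' @param output_shape Length-3: (slices, height, width) of the output.
#' @param enc_channels Five encoder channel widths.
#' @param enc_pools List of five length-3 pooling factors (depth, h, w);
#'   `c(1,1,1)` disables pooling for a block.
#' @param bottleneck Width of the fully connected bottleneck.
#' @param dec_channels Five decoder channel widths.
#' @param dec_strides List of five length-3 transposed-conv strides.
#' @param dec_start_channels Channels of the FC-reshaped decoder seed map.
#' @param skip Enable encoder-decoder skip connections.
#' @param dual_sampling Enable the dual-sampling attention modules.
#' @param leaky_slope Negative slope of the encoder LeakyReLU.
#' @param out_bias_init Initial bias of the output head.
#' @param output_activation Non-negativity of the reconstruction:
#'   `"linear_clamp"` trains a linear head and clamps predictions at zero in
#'   inference (saturating heads stall on the mostly-empty target volumes);
#'   `"softplus"` is smooth and non-negative end to end.
#' @return An object of class `net_config` with derived per-stage shapes.
#' @export
net_config <- function(input_shape, output_shape,
                       enc_channels, enc_pools, bottleneck,
                       dec_channels, dec_strides, dec_start_channels,
                       skip = TRUE, dual_sampling = TRUE,
                       leaky_slope = 0.2, out_bias_init = 0,
                       output_activation = c("linear_clamp", "softplus")) {
  output_activation <- match.arg(output_activation)
  stop_if_not(length(enc_channels) == 5 && length(enc_pools) == 5,
              "the encoder has five blocks")
  stop_if_not(length(dec_channels) == 5 && length(dec_strides) == 5,
              "the decoder has five blocks")
  enc_shapes <- vector("list", 6)
  enc_shapes[[1]] <- as.integer(input_shape)
  for (k in 1:5) {
    s <- enc_shapes[[k]]
    p <- enc_pools[[k]]
    stop_if_not(all(s %% p == 0),
                sprintf("encoder block %d: shape not divisible by pool", k))
    enc_shapes[[k + 1]] <- as.integer(s / p)
  }
  up <- Reduce(`*`, dec_strides)
  stop_if_not(all(output_shape %% up == 0),
              "output shape must be divisible by the decoder upsampling")
  dec_shapes <- vector("list", 6)
  dec_shapes[[1]] <- as.integer(output_shape / up)
  for (k in 1:5) dec_shapes[[k + 1]] <- as.integer(dec_shapes[[k]] * dec_strides[[k]])
  stop_if_not(all(dec_shapes[[6]] == output_shape), "decoder shape chain broken")
  structure(list(
    input_shape = as.integer(input_shape),
    output_shape = as.integer(output_shape),
    enc_channels = as.integer(enc_channels), enc_pools = enc_pools,
    enc_shapes = enc_shapes,
    bottleneck = as.integer(bottleneck),
    dec_channels = as.integer(dec_channels), dec_strides = dec_strides,
    dec_shapes = dec_shapes,
    dec_start_channels = as.integer(dec_start_channels),
    skip = isTRUE(skip), dual_sampling = isTRUE(dual_sampling),
    leaky_slope = leaky_slope, out_bias_init = out_bias_init,
    output_activation = output_activation
  ), class = "net_config")
}

#' @rdname net_config
#' @param ... Overrides passed to [net_config()] fields.
#' @export
net_config_full <- function(...) {
  args <- list(
    input_shape = c(24, 128, 128), output_shape = c(7, 128, 128),
    enc_channels = c(16, 32, 64, 128, 256),
    enc_pools = list(c(2, 2, 2), c(2, 2, 2), c(2, 2, 2),
                     c(1, 2, 2), c(1, 2, 2)),
    bottleneck = 1024,
    dec_channels = c(256, 128, 64, 32, 16),
    dec_strides = list(c(1, 2, 2), c(1, 2, 2), c(1, 2, 2),
                       c(1, 2, 2), c(1, 2, 2)),
    dec_start_channels = 256,
    output_activation = "softplus", out_bias_init = -1
  )
  args[names(list(...))] <- list(...)
  do.call(net_config, args)
}

#' @rdname net_config
#' @export
net_config_scaled <- function(...) {
  args <- list(
    input_shape = c(12, 48, 48), output_shape = c(5, 48, 48),
    enc_channels = c(4, 8, 16, 16, 16),
    enc_pools = list(c(2, 2, 2), c(2, 2, 2), c(1, 2, 2),
                     c(1, 2, 2), c(1, 1, 1)),
    bottleneck = 512,
    dec_channels = c(16, 16, 8, 4, 4),
    dec_strides = list(c(1, 2, 2), c(1, 2, 2), c(1, 2, 2),
                       c(1, 2, 2), c(1, 1, 1)),
    dec_start_channels = 16,
    output_activation = "softplus", out_bias_init = -1,
    dual_sampling = FALSE
  )
  args[names(list(...))] <- list(...)
  do.call(net_config, args)
}

# Skip source for decoder stage i: encoder block (6 - i) output.
skip_source <- function(i) 6L - as.integer(i)

dec_in_channels <- function(config, i) {
  base <- if (i == 1) config$dec_start_channels else config$dec_channels[i - 1]
  if (config$skip) base + config$enc_channels[skip_source(i)] else base
}

#' Build a reconstruction network from a configuration
#'
#' Initializes all parameters (He-scaled Gaussian weights, unit batch-norm
#' gains) reproducibly from the seed.
#'
#' @param config A [net_config()].
#' @param seed Integer seed for the initialization draw.
#' @return An object of class `xlct_network` holding parameter environments
#'   and a flat parameter index for the optimizer.
#' @export
build_network <- function(config, seed = 1) {
  stop_if_not(inherits(config, "net_config"), "`config` must be a net_config")
  set.seed(as.integer(seed))
  he <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
  conv_block <- function(ci, co) new_param_env(list(
    w = he(c(3, 3, 3, ci, co), 27 * ci), b = numeric(co),
    gamma = rep(1, co), beta = numeric(co),
    rm = numeric(co), rv = rep(1, co)))
  enc <- vector("list", 5)
  ci <- 1L
  for (k in 1:5) {
    enc[[k]] <- conv_block(ci, config$enc_channels[k])
    ci <- config$enc_channels[k]
  }
  flat_in <- prod(config$enc_shapes[[6]]) * config$enc_channels[5]
  flat_out <- prod(config$dec_shapes[[1]]) * config$dec_start_channels
  fc1 <- new_param_env(list(w = he(c(flat_in, config$bottleneck), flat_in),
                            b = numeric(config$bottleneck)))
  fc2 <- new_param_env(list(w = he(c(config$bottleneck, flat_out), config$bottleneck),
                            b = numeric(flat_out)))
  dec <- vector("list", 5)
  for (k in 1:5) {
    cin <- dec_in_channels(config, k)
    co <- config$dec_channels[k]
    pars <- list(
      # transposed conv: underlying conv maps co -> cin, weights (3,3,3,co,cin)
      w = he(c(3, 3, 3, co, cin), 27 * cin), b = numeric(co),
      gamma = rep(1, co), beta = numeric(co),
      rm = numeric(co), rv = rep(1, co))
    if (config$dual_sampling) {
      # small init keeps the channel gates near their neutral value (0.5)
      # early in training; large random gates throttle whole channels
      cm <- max(1L, co %/% 2L)
      pars <- c(pars, list(w1 = he(c(co, cm), co) * 0.1, b1 = numeric(cm),
                           w2 = he(c(cm, co), cm) * 0.1, b2 = numeric(co)))
    }
    dec[[k]] <- new_param_env(pars)
  }
  # the softplus head starts near (but not at) zero on the mostly-empty
  # target volumes; a negative bias keeps the initial background small while
  # gradients still flow
  out <- new_param_env(list(w = he(c(1, 1, 1, config$dec_channels[5], 1),
                                   config$dec_channels[5]),
                            b = config$out_bias_init))
  envs <- c(enc, list(fc1, fc2), dec, list(out))
  names(envs) <- c(paste0("enc", 1:5), "fc1", "fc2", paste0("dec", 1:5), "out")
  param_index <- list()
  for (nm in names(envs)) {
    for (p in setdiff(ls(envs[[nm]]), c("rm", "rv"))) {
      param_index[[length(param_index) + 1]] <- list(env = envs[[nm]], name = p,
                                                     label = paste0(nm, ".", p))
    }
  }
  structure(list(config = config, enc = enc, fc1 = fc1, fc2 = fc2,
                 dec = dec, out = out, envs = envs,
                 param_index = param_index),
            class = "xlct_network")
}

#' Number of trainable parameters
#'
#' @param network An [build_network()] object.
#' @return Integer parameter count.
#' @export
count_parameters <- function(network) {
  sum(vapply(network$param_index,
             function(p) length(get(p$name, envir = p$env)), numeric(1)))
}

#' @export
print.xlct_network <- function(x, ...) {
  cat(sprintf("xlct_network: (%s) -> (%s), %s parameters, skip=%s, attention=%s\n",
              paste(x$config$input_shape, collapse = "x"),
              paste(x$config$output_shape, collapse = "x"),
              format(count_parameters(x), big.mark = ","),
              x$config$skip, x$config$dual_sampling))
  invisible(x)
}

# Forward pass. x: (D, H, W, 1, B). Returns y and (if keep_cache) all
# intermediates needed by network_backward.
network_forward <- function(net, x, training = FALSE, keep_cache = training) {
  cfg <- net$config
  cache <- list(x = x)
  enc_out <- vector("list", 5)
  h <- x
  for (k in 1:5) {
    e <- net$enc[[k]]
    cv <- conv_fwd(h, e$w, e$b)
    bn <- bn_fwd(cv, e, training)
    ac <- leaky_fwd(bn$y, cfg$leaky_slope)
    pool <- cfg$enc_pools[[k]]
    if (any(pool > 1)) {
      mp <- cpp_maxpool3d_fwd(ac$y, dim(ac$y), as.integer(pool))
      h2 <- mp$y
      if (keep_cache) cache[[paste0("enc", k)]] <-
          list(x_in = h, bn = bn$cache, act = ac$y, argmax = mp$argmax,
               prepool_dim = dim(ac$y))
    } else {
      h2 <- ac$y
      if (keep_cache) cache[[paste0("enc", k)]] <-
          list(x_in = h, bn = bn$cache, act = ac$y, argmax = NULL,
               prepool_dim = dim(ac$y))
    }
    enc_out[[k]] <- h2
    h <- h2
  }
  B <- dim(x)[5]
  flat <- matrix(h, ncol = B)
  f1 <- t(net$fc1$w) %*% flat + net$fc1$b
  a1 <- leaky_fwd(f1, cfg$leaky_slope)
  f2 <- t(net$fc2$w) %*% a1$y + net$fc2$b
  a2 <- leaky_fwd(f2, cfg$leaky_slope)
  if (keep_cache) cache$fc <- list(flat = flat, h1 = a1$y, h2 = a2$y,
                                   enc_dim = dim(h))
  h <- array(a2$y, c(cfg$dec_shapes[[1]], cfg$dec_start_channels, B))
  for (k in 1:5) {
    dcache <- list()
    if (cfg$skip) {
      src <- enc_out[[skip_source(k)]]
      r <- resize_nearest(src, dim(h)[1:3])
      dcache$skip_in_dim <- dim(src)
      dcache$skip_res <- attr(r, "resize_src")
      dcache$n_main <- dim(h)[4]
      h <- abind_channels(h, r)
    }
    e <- net$dec[[k]]
    dcache$x_in <- h
    tv <- tconv_fwd(h, e$w, e$b, cfg$dec_strides[[k]])
    bn <- bn_fwd(tv, e, training)
    ac <- relu_fwd(bn$y)
    dcache$bn <- bn$cache
    dcache$act <- ac$y
    h <- ac$y
    if (cfg$dual_sampling) {
      at <- attention_fwd(h, e)
      dcache$att <- at$cache
      h <- at$y
    }
    if (keep_cache) cache[[paste0("dec", k)]] <- dcache
  }
  ov <- conv_fwd(h, net$out$w, net$out$b, stride = c(1L, 1L, 1L),
                 pad = c(0L, 0L, 0L))
  if (cfg$output_activation == "softplus") {
    oa <- softplus_fwd(ov)
    yout <- oa$y
  } else {
    yout <- if (training) ov else cpp_relu_fwd(ov)
  }
  if (keep_cache) {
    cache$out <- list(x_in = h, z = ov)
    cache$y <- yout
  }
  list(y = yout, cache = if (keep_cache) cache else NULL)
}

abind_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4], da[5]))
  out[, , , seq_len(da[4]), ] <- a
  out[, , , da[4] + seq_len(db[4]), ] <- b
  out
}

# Backward pass: accumulates parameter gradients into the network's
# environments and returns the input gradient.
network_backward <- function(net, cache, dy) {
  cfg <- net$config
  g <- if (cfg$output_activation == "softplus") {
    softplus_bwd(dy, cache$out$z)
  } else dy
  cb <- conv_bwd(cache$out$x_in, net$out$w, g, stride = c(1L, 1L, 1L),
                 pad = c(0L, 0L, 0L))
  acc_grad(net$out, "w", cb$dw); acc_grad(net$out, "b", cb$db)
  g <- cb$dx
  skip_grads <- vector("list", 5)
  for (k in 5:1) {
    e <- net$dec[[k]]
    dc <- cache[[paste0("dec", k)]]
    if (cfg$dual_sampling) g <- attention_bwd(g, e, dc$att)
    g <- relu_bwd(g, dc$act)
    g <- bn_bwd(g, e, dc$bn)
    tb <- tconv_bwd(dc$x_in, e$w, g, cfg$dec_strides[[k]])
    acc_grad(e, "w", tb$dw); acc_grad(e, "b", tb$db)
    g <- tb$dx
    if (cfg$skip) {
      nm <- dc$n_main
      gs <- g[, , , (nm + 1):dim(g)[4], , drop = FALSE]
      attr(gs, "resize_src") <- dc$skip_res
      skip_grads[[skip_source(k)]] <- resize_nearest_bwd(gs, dc$skip_in_dim[1:3])
      g <- g[, , , seq_len(nm), , drop = FALSE]
    }
  }
  B <- dim(g)[5]
  gflat <- matrix(g, ncol = B)
  gflat <- leaky_bwd(gflat, cache$fc$h2, cfg$leaky_slope)
  acc_grad(net$fc2, "w", cache$fc$h1 %*% t(gflat))
  acc_grad(net$fc2, "b", rowSums(gflat))
  g1 <- net$fc2$w %*% gflat
  g1 <- leaky_bwd(g1, cache$fc$h1, cfg$leaky_slope)
  acc_grad(net$fc1, "w", cache$fc$flat %*% t(g1))
  acc_grad(net$fc1, "b", rowSums(g1))
  g <- array(net$fc1$w %*% g1, cache$fc$enc_dim)
  for (k in 5:1) {
    if (!is.null(skip_grads[[k]])) g <- g + skip_grads[[k]]
    e <- net$enc[[k]]
    ec <- cache[[paste0("enc", k)]]
    if (!is.null(ec$argmax)) {
      g <- cpp_maxpool3d_bwd(g, ec$argmax, as.integer(ec$prepool_dim))
    }
    g <- leaky_bwd(g, ec$act, cfg$leaky_slope)
    g <- bn_bwd(g, e, ec$bn)
    cb <- conv_bwd(ec$x_in, e$w, g)
    acc_grad(e, "w", cb$dw); acc_grad(e, "b", cb$db)
    g <- cb$dx
  }
  g
}

# Snapshot / restore all parameters (including batch-norm running stats).
snapshot_params <- function(net) {
  lapply(net$envs, function(e) mget(setdiff(ls(e), grep("^g_", ls(e), value = TRUE)),
                                    envir = e))
}

restore_params <- function(net, snapshot) {
  for (nm in names(snapshot)) {
    for (p in names(snapshot[[nm]])) assign(p, snapshot[[nm]][[p]],
                                            envir = net$envs[[nm]])
  }
  invisible(net)
}
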