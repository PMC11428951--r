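# Differentiable building blocks of the reconstruction network. Tensors are
# numeric arrays with layout (D, H, W, C, B). Parameters live in
# environments so gradient accumulation and optimizer updates mutate in
# place; each block's backward pass writes grads as `g_<name>` next to the
# parameter.

new_param_env <- function(params) {
  e <- new.env(parent = emptyenv())
  for (nm in names(params)) assign(nm, params[[nm]], envir = e)
  e
}

zero_grads <- function(env) {
  for (nm in ls(env)) {
    if (startsWith(nm, "g_")) assign(nm, NULL, envir = env)
  }
}

acc_grad <- function(env, name, g) {
  gn <- paste0("g_", name)
  cur <- if (exists(gn, envir = env, inherits = FALSE)) get(gn, envir = env) else NULL
  assign(gn, if (is.null(cur)) g else cur + g, envir = env)
}

# ---- convolution wrappers (pad = same for kernel 3, stride 1) ----

conv_fwd <- function(x, w, b, stride = c(1L, 1L, 1L), pad = c(1L, 1L, 1L)) {
  cpp_conv3d_fwd(x, dim(x), w, dim(w), b, as.integer(stride), as.integer(pad))
}

conv_bwd <- function(x, w, dy, stride = c(1L, 1L, 1L), pad = c(1L, 1L, 1L)) {
  list(dx = cpp_conv3d_bwd_data(dy, w, dim(w), dim(x), as.integer(stride),
                                as.integer(pad)),
       dw = cpp_conv3d_bwd_w(x, dim(x), dy, dim(w), as.integer(stride),
                             as.integer(pad)),
       db = channel_sums(dy))
}

# Transposed convolution with stride s: forward is the data-gradient of a
# stride-s convolution, so upsampled output dims are input dims times s.
tconv_fwd <- function(x, w, b, stride) {
  d <- dim(x)
  ydim <- c(d[1:3] * stride, dim(w)[4], d[5])
  y <- cpp_conv3d_bwd_data(x, w, dim(w), as.integer(ydim),
                           as.integer(stride), c(1L, 1L, 1L))
  add_channel_bias(y, b)
}

tconv_bwd <- function(x, w, dy, stride) {
  d <- dim(x)
  ydim <- c(d[1:3] * stride, dim(w)[4], d[5])
  list(dx = cpp_conv3d_fwd(dy, as.integer(ydim), w, dim(w),
                           numeric(dim(w)[5]), as.integer(stride),
                           c(1L, 1L, 1L)),
       dw = cpp_conv3d_bwd_w(dy, as.integer(ydim), x, dim(w),
                             as.integer(stride), c(1L, 1L, 1L)),
       db = channel_sums(dy))
}

# Per-channel reductions without transposing: a (D,H,W,C,B) tensor viewed as
# a (D*H*W, C*B) matrix has channel c in columns c, c+C, c+2C, ...; column
# statistics fold into per-channel ones via a C x B reshape.

channel_sums <- function(y) {
  d <- dim(y)
  rowSums(matrix(colSums(matrix(y, prod(d[1:3]))), d[4], d[5]))
}

add_channel_bias <- function(y, b) {
  v <- prod(dim(y)[1:3])
  y + rep(b, each = v)  # recycles over the batch axis
}

# ---- batch normalization over (D, H, W, B) per channel ----

bn_fwd <- function(x, env, training, eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  v <- prod(d[1:3]); C <- d[4]; B <- d[5]
  xm <- matrix(x, v)
  n_tot <- v * B
  if (training) {
    mu <- rowSums(matrix(colSums(xm), C, B)) / n_tot
    ex2 <- rowSums(matrix(colSums(xm^2), C, B)) / n_tot
    va <- pmax(ex2 - mu^2, 0)
    env$rm <- (1 - momentum) * env$rm + momentum * mu
    env$rv <- (1 - momentum) * env$rv + momentum * va
  } else {
    mu <- env$rm
    va <- env$rv
  }
  istd <- 1 / sqrt(va + eps)
  gc <- rep.int(seq_len(C), B)
  xhat <- cpp_colscale_add(xm, v, istd[gc], -(mu * istd)[gc])
  y <- cpp_colscale_add(xhat, v, env$gamma[gc], env$beta[gc])
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, istd = istd, dims = d, gc = gc,
                           training = training))
}

bn_bwd <- function(dy, env, cache) {
  d <- cache$dims
  v <- prod(d[1:3]); C <- d[4]; B <- d[5]
  gc <- cache$gc
  n_tot <- v * B
  dym <- matrix(dy, v)
  xhat <- cache$xhat
  acc_grad(env, "beta", rowSums(matrix(colSums(dym), C, B)))
  acc_grad(env, "gamma", rowSums(matrix(colSums(dym * xhat), C, B)))
  dxhat <- cpp_colscale_add(dym, v, env$gamma[gc], numeric(C * B))
  dim(dxhat) <- c(v, C * B)
  if (cache$training) {
    m1 <- rowSums(matrix(colSums(dxhat), C, B)) / n_tot
    m2 <- rowSums(matrix(colSums(dxhat * xhat), C, B)) / n_tot
    dxm <- cpp_bn_bwd_fuse(dxhat, xhat, v, m1[gc], m2[gc], cache$istd[gc])
  } else {
    dxm <- cpp_colscale_add(dxhat, v, cache$istd[gc], numeric(C * B))
  }
  dim(dxm) <- d
  dxm
}

# ---- activations (backward recovers the active set from the output) ----

leaky_fwd <- function(x, slope) list(y = cpp_leaky_fwd(x, slope))

leaky_bwd <- function(dy, y, slope) cpp_leaky_bwd(dy, y, slope)

relu_fwd <- function(x) list(y = cpp_relu_fwd(x))

relu_bwd <- function(dy, y) cpp_relu_bwd(dy, y)

# ---- nearest-neighbour 3D resize (skip-connection adapter) ----

resize_nearest <- function(x, out_dhw) {
  d <- dim(x)
  src <- lapply(1:3, function(k) {
    pmin(d[k], floor((seq_len(out_dhw[k]) - 0.5) * d[k] / out_dhw[k]) + 1L)
  })
  y <- x[src[[1]], src[[2]], src[[3]], , , drop = FALSE]
  attr(y, "resize_src") <- src
  y
}

resize_nearest_bwd <- function(dy, in_dhw) {
  d <- dim(dy)
  src <- attr(dy, "resize_src")
  if (is.null(src)) {
    src <- lapply(1:3, function(k) {
      pmin(in_dhw[k], floor((seq_len(d[k]) - 0.5) * in_dhw[k] / d[k]) + 1L)
    })
  }
  lin_out <- as.vector(outer(outer(src[[1]], (src[[2]] - 1L) * in_dhw[1], "+"),
                             (src[[3]] - 1L) * in_dhw[1] * in_dhw[2], "+"))
  cb <- d[4] * d[5]
  dym <- matrix(dy, ncol = cb)
  agg <- rowsum(dym, lin_out)
  dxm <- matrix(0, prod(in_dhw), cb)
  dxm[as.integer(rownames(agg)), ] <- agg
  array(dxm, c(in_dhw, d[4], d[5]))
}

# ---- dual-sampling channel attention ----
# Parallel global average- and max-pool descriptors feed a shared two-layer
# MLP; the summed outputs pass through a sigmoid and rescale the channels.

attention_fwd <- function(x, env) {
  d <- dim(x)
  v <- prod(d[1:3])
  xm <- matrix(x, v)                       # v x (C*B)
  avg <- colMeans(xm)
  amax_i <- max.col(t(xm), ties.method = "first")
  mx <- xm[cbind(amax_i, seq_len(ncol(xm)))]
  A <- matrix(avg, d[4], d[5])
  Mx <- matrix(mx, d[4], d[5])
  h_a <- pmax(t(env$w1) %*% A + env$b1, 0)
  h_m <- pmax(t(env$w1) %*% Mx + env$b1, 0)
  z <- t(env$w2) %*% (h_a + h_m) + env$b2
  a <- 1 / (1 + exp(-z))                   # C x B
  y <- xm * rep(as.vector(a), each = v)
  list(y = array(y, d),
       cache = list(xm = xm, A = A, Mx = Mx, h_a = h_a, h_m = h_m,
                    a = a, amax_i = amax_i, dims = d))
}

attention_bwd <- function(dy, env, cache) {
  d <- cache$dims
  v <- prod(d[1:3])
  gm <- matrix(dy, v)
  av <- rep(as.vector(cache$a), each = v)
  dx <- gm * av
  da <- matrix(colSums(gm * cache$xm), d[4], d[5])
  dz <- da * cache$a * (1 - cache$a)
  dh <- env$w2 %*% dz
  dh_a <- dh * (cache$h_a > 0)
  dh_m <- dh * (cache$h_m > 0)
  acc_grad(env, "w2", cache$h_a %*% t(dz) + cache$h_m %*% t(dz))
  acc_grad(env, "b2", rowSums(dz))
  acc_grad(env, "w1", cache$A %*% t(dh_a) + cache$Mx %*% t(dh_m))
  acc_grad(env, "b1", rowSums(dh_a + dh_m))
  dA <- env$w1 %*% dh_a
  dMx <- env$w1 %*% dh_m
  dx <- dx + matrix(rep(as.vector(dA) / v, each = v), v)
  dxm_max <- cbind(cache$amax_i, seq_len(ncol(gm)))
  dx[dxm_max] <- dx[dxm_max] + as.vector(dMx)
  array(dx, d)
}

# ---- Adam optimizer over an environment-based parameter index ----

adam_init <- function(param_index) {
  lapply(param_index, function(p) {
    val <- get(p$name, envir = p$env)
    list(m = val * 0, v = val * 0)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(param_index, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(param_index)) {
    p <- param_index[[i]]
    gn <- paste0("g_", p$name)
    g <- get(gn, envir = p$env)
    if (is.null(g)) next
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    state[[i]] <- st
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    val <- get(p$name, envir = p$env)
    assign(p$name, val - lr * mhat / (sqrt(vhat) + eps), envir = p$env)
  }
  state
}

# Softplus output head: smooth non-negative activation log(1 + exp(z));
# unlike a hard ReLU it cannot die on sparse targets.
softplus_fwd <- function(z) {
  y <- ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
  dim(y) <- dim(z)
  list(y = y)
}

softplus_bwd <- function(dy, z) {
  g <- dy * stats::plogis(z)
  dim(g) <- dim(dy)
  g
}
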