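# Training objective: mean squared error plus structural-similarity loss,
# each evaluated on the full volume and on the target-region (ROI) crop,
#     L = L_MSE(xr, xt) + L_MSE(xr', xt') + 2 [L_SSIM(xr, xt) + L_SSIM(xr', xt')]
# with L_SSIM = 1 - MSSIM. SSIM uses an 11 x 11 Gaussian window (sigma 1.5)
# slid over every 2D z-slice ("valid" positions, no padding), averaged over
# all window positions and slices. Analytic gradients are provided for
# network training and are finite-difference checked in the test suite.

#' SSIM parameters
#'
#' Gaussian window and stabilization constants of the structural similarity
#' index: window size 11, sigma 1.5, `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`
#' with `L` the data dynamic range (1 after max-normalization).
#'
#' @param window_size Odd window side length.
#' @param sigma Gaussian window standard deviation (pixels).
#' @param k1,k2 Stabilization fractions of the dynamic range.
#' @param L Dynamic range of the data.
#' @return An object of class `ssim_params`.
#' @export
ssim_params <- function(window_size = 11, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                        L = 1) {
  stop_if_not(window_size %% 2 == 1 && window_size >= 3,
              "`window_size` must be odd and >= 3")
  check_positive_scalar(sigma, "sigma")
  g <- exp(-((seq_len(window_size) - (window_size + 1) / 2)^2) / (2 * sigma^2))
  g <- g / sum(g)
  structure(list(window_size = window_size, sigma = sigma,
                 window = g, C1 = (k1 * L)^2, C2 = (k2 * L)^2, L = L),
            class = "ssim_params")
}

# Valid-mode 1D correlation operator ((n - w + 1) x n) for a window g.
window_conv_matrix <- function(n, g) {
  w <- length(g)
  stop_if_not(n >= w, "image smaller than the SSIM window")
  m <- matrix(0, n - w + 1, n)
  for (i in seq_len(n - w + 1)) m[i, i:(i + w - 1)] <- g
  m
}

.conv_cache <- new.env(parent = emptyenv())
get_conv_mats <- function(h, w, params) {
  key <- sprintf("%d_%d_%d_%g", h, w, params$window_size, params$sigma)
  if (is.null(.conv_cache[[key]])) {
    .conv_cache[[key]] <- list(Ch = window_conv_matrix(h, params$window),
                               Cw = window_conv_matrix(w, params$window))
  }
  .conv_cache[[key]]
}

#' Structural similarity of a single patch pair
#'
#' SSIM of two equally shaped patches using Gaussian weights (the params
#' window when shapes match it, otherwise a same-shape Gaussian with the
#' params sigma):
#' `(2 mu_r mu_t + C1)(2 sigma_rt + C2) / ((mu_r^2 + mu_t^2 + C1)(sigma_r^2 + sigma_t^2 + C2))`.
#' Values lie in `[-1, 1]`, equal 1 for identical patches, and are symmetric
#' in the two arguments.
#'
#' @param patch_r,patch_t Numeric matrices of identical shape.
#' @param params An [ssim_params()].
#' @return A single SSIM value.
#' @export
local_ssim <- function(patch_r, patch_t, params = ssim_params()) {
  stop_if_not(all(dim(patch_r) == dim(patch_t)), "patches must share a shape")
  gh <- if (nrow(patch_r) == params$window_size) params$window else {
    g <- exp(-((seq_len(nrow(patch_r)) - (nrow(patch_r) + 1) / 2)^2) /
               (2 * params$sigma^2)); g / sum(g)
  }
  gw <- if (ncol(patch_r) == params$window_size) params$window else {
    g <- exp(-((seq_len(ncol(patch_r)) - (ncol(patch_r) + 1) / 2)^2) /
               (2 * params$sigma^2)); g / sum(g)
  }
  wgt <- outer(gh, gw)
  mu_r <- sum(wgt * patch_r); mu_t <- sum(wgt * patch_t)
  v_r <- sum(wgt * patch_r^2) - mu_r^2
  v_t <- sum(wgt * patch_t^2) - mu_t^2
  cov <- sum(wgt * patch_r * patch_t) - mu_r * mu_t
  ((2 * mu_r * mu_t + params$C1) * (2 * cov + params$C2)) /
    ((mu_r^2 + mu_t^2 + params$C1) * (v_r + v_t + params$C2))
}

# SSIM map of one 2D slice pair at all valid window positions, with the
# intermediates needed for the gradient.
ssim_slice <- function(X, Y, params, want_grad = FALSE) {
  cm <- get_conv_mats(nrow(X), ncol(X), params)
  Ch <- cm$Ch; Cw <- cm$Cw
  mx <- Ch %*% X %*% t(Cw); my <- Ch %*% Y %*% t(Cw)
  sxx <- Ch %*% (X * X) %*% t(Cw) - mx^2
  syy <- Ch %*% (Y * Y) %*% t(Cw) - my^2
  sxy <- Ch %*% (X * Y) %*% t(Cw) - mx * my
  A1 <- 2 * mx * my + params$C1
  A2 <- 2 * sxy + params$C2
  B1 <- mx^2 + my^2 + params$C1
  B2 <- sxx + syy + params$C2
  S <- (A1 * A2) / (B1 * B2)
  if (!want_grad) return(list(S = S))
  # partials of S wrt the window statistics of X
  dS_dmx <- 2 * my * A2 / (B1 * B2) - 2 * mx * A1 * A2 / (B1^2 * B2)
  dS_dsxx <- -A1 * A2 / (B1 * B2^2)
  dS_dsxy <- 2 * A1 / (B1 * B2)
  list(S = S, mx = mx, my = my,
       dS_dmx = dS_dmx, dS_dsxx = dS_dsxx, dS_dsxy = dS_dsxy,
       Ch = Ch, Cw = Cw)
}

# Gradient of sum(S) over the slice wrt X, given ssim_slice(want_grad=TRUE).
ssim_slice_grad <- function(sl, X, Y) {
  Gmu <- sl$dS_dmx - 2 * sl$mx * sl$dS_dsxx - sl$my * sl$dS_dsxy
  t(sl$Ch) %*% Gmu %*% sl$Cw +
    2 * X * (t(sl$Ch) %*% sl$dS_dsxx %*% sl$Cw) +
    Y * (t(sl$Ch) %*% sl$dS_dsxy %*% sl$Cw)
}

as_slices <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1)) else {
    stop_if_not(is.array(x) && length(dim(x)) == 3, "expected a 2D or 3D array")
    x
  }
}

#' Mean structural similarity of two volumes
#'
#' Mean of the Gaussian-windowed SSIM over all valid 2D window positions of
#' every z-slice. Equals 1 for identical volumes and lies in `[-1, 1]`.
#'
#' @param xr,xt Equally shaped matrices or 3D arrays (slices along dim 3).
#' @param params An [ssim_params()].
#' @return Scalar MSSIM.
#' @export
mssim <- function(xr, xt, params = ssim_params()) {
  xr <- as_slices(xr); xt <- as_slices(xt)
  stop_if_not(all(dim(xr) == dim(xt)), "shape mismatch")
  tot <- 0; m <- 0
  for (k in seq_len(dim(xr)[3])) {
    S <- ssim_slice(xr[, , k], xt[, , k], params)$S
    tot <- tot + sum(S); m <- m + length(S)
  }
  tot / m
}

#' Structural-similarity loss
#'
#' `1 - mssim(xr, xt)`: zero iff MSSIM is 1, at most 2.
#'
#' @inheritParams mssim
#' @return Scalar loss in `[0, 2]`.
#' @export
ssim_loss <- function(xr, xt, params = ssim_params()) {
  1 - mssim(xr, xt, params)
}

#' Mean squared error loss
#'
#' @param xr,xt Equally shaped numeric arrays.
#' @return `mean((xr - xt)^2)`.
#' @export
mse_loss <- function(xr, xt) {
  stop_if_not(all(dim(xr) == dim(xt)) || length(xr) == length(xt),
              "shape mismatch")
  mean((xr - xt)^2)
}

# ROI bounding box of a logical mask, expanded in-plane so the SSIM window
# fits, as index ranges per dimension.
roi_bounding_box <- function(roi_mask, min_size = 11) {
  stop_if_not(any(roi_mask), "empty ROI")
  idx <- which(roi_mask, arr.ind = TRUE)
  dims <- dim(roi_mask)
  box <- lapply(1:3, function(d) range(idx[, d]))
  for (d in 1:2) {
    lo <- box[[d]][1]; hi <- box[[d]][2]
    need <- min_size - (hi - lo + 1)
    if (need > 0) {
      lo <- max(1, lo - ceiling(need / 2))
      hi <- min(dims[d], lo + min_size - 1)
      lo <- max(1, hi - min_size + 1)
    }
    stop_if_not(hi - lo + 1 >= min_size,
                "volume too small for the SSIM window over the ROI")
    box[[d]] <- c(lo, hi)
  }
  box
}

#' Composite reconstruction training loss
#'
#' Decomposed objective: full-volume MSE, ROI MSE, and SSIM losses on both,
#' the SSIM terms carrying weight 2:
#' `total = mse_full + mse_roi + 2 * (ssim_loss_full + ssim_loss_roi)`.
#' ROI terms are evaluated on the bounding-box crop of the ROI mask
#' (expanded in-plane to fit the SSIM window).
#'
#' @param xr Reconstructed volume (3D array, slices along dim 3).
#' @param xt Ground-truth volume, same shape.
#' @param roi_mask Non-empty logical array, same shape.
#' @param params An [ssim_params()].
#' @param want_grad Also return the analytic gradient wrt `xr`.
#' @return Object of class `loss_components` with fields `mse_full`,
#'   `mse_roi`, `ssim_loss_full`, `ssim_loss_roi`, `total` (and `grad` if
#'   requested).
#' @export
composite_loss <- function(xr, xt, roi_mask, params = ssim_params(),
                           want_grad = FALSE) {
  xr <- as_slices(xr); xt <- as_slices(xt)
  stop_if_not(all(dim(xr) == dim(xt)), "shape mismatch")
  stop_if_not(any(roi_mask), "empty ROI")
  box <- roi_bounding_box(array(roi_mask, dim(xr)), params$window_size)
  rx <- box[[1]][1]:box[[1]][2]; ry <- box[[2]][1]:box[[2]][2]
  rz <- box[[3]][1]:box[[3]][2]
  xr_roi <- xr[rx, ry, rz, drop = FALSE]
  xt_roi <- xt[rx, ry, rz, drop = FALSE]

  mse_full <- mse_loss(xr, xt)
  mse_roi <- mse_loss(xr_roi, xt_roi)

  grad <- if (want_grad) array(0, dim(xr)) else NULL
  ssim_sum <- function(a, b, gacc_idx = NULL) {
    tot <- 0; m <- 0
    g <- if (want_grad) array(0, dim(a)) else NULL
    for (k in seq_len(dim(a)[3])) {
      sl <- ssim_slice(a[, , k], b[, , k], params, want_grad = want_grad)
      tot <- tot + sum(sl$S); m <- m + length(sl$S)
      if (want_grad) g[, , k] <- ssim_slice_grad(sl, a[, , k], b[, , k])
    }
    list(mssim = tot / m, grad_mssim = if (want_grad) g / m else NULL)
  }
  sf <- ssim_sum(xr, xt)
  sr <- ssim_sum(xr_roi, xt_roi)
  ssim_loss_full <- 1 - sf$mssim
  ssim_loss_roi <- 1 - sr$mssim
  total <- mse_full + mse_roi + 2 * (ssim_loss_full + ssim_loss_roi)

  out <- structure(list(mse_full = mse_full, mse_roi = mse_roi,
                        ssim_loss_full = ssim_loss_full,
                        ssim_loss_roi = ssim_loss_roi, total = total),
                   class = "loss_components")
  if (want_grad) {
    g <- 2 * (xr - xt) / length(xr)          # d mse_full
    g_roi <- 2 * (xr_roi - xt_roi) / length(xr_roi)
    g[rx, ry, rz] <- g[rx, ry, rz, drop = FALSE] + g_roi   # d mse_roi
    g <- g - 2 * sf$grad_mssim               # d 2*(1 - mssim_full)
    g[rx, ry, rz] <- g[rx, ry, rz, drop = FALSE] - 2 * sr$grad_mssim
    out$grad <- g
  }
  out
}

#' @export
print.loss_components <- function(x, ...) {
  cat(sprintf(paste0("loss: total %.6g = mse_full %.4g + mse_roi %.4g",
                     " + 2*(ssim %.4g + ssim_roi %.4g)\n"),
              x$total, x$mse_full, x$mse_roi,
              x$ssim_loss_full, x$ssim_loss_roi))
  invisible(x)
}
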