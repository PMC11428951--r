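# Quantitative evaluation of reconstructions: max-normalization, the Dice
# similarity coefficient between thresholded reconstruction and truth, the
# volume-weighted contrast-to-noise ratio, line profiles, and connected
# components for resolvability checks.

#' Max-normalize a volume
#'
#' Divides by the maximum intensity so the maximum becomes 1; ordering of
#' voxel values is preserved and the operation is idempotent. An all-zero
#' volume is returned unchanged with a warning.
#'
#' @param volume Numeric array.
#' @return Normalized volume.
#' @export
normalize_volume <- function(volume) {
  m <- max(volume)
  if (m <= 0) {
    warning("all-zero volume: returned unchanged")
    return(volume)
  }
  volume / m
}

#' Dice similarity coefficient
#'
#' Binarizes the (max-normalized) reconstruction at `threshold_frac` of its
#' maximum and computes `2 |A intersect B| / (|A| + |B|)` against the true
#' target region. Because the threshold is relative, the value is invariant
#' to any monotone rescaling of the reconstruction. If both regions are
#' empty the coefficient is defined as 1 (with a message).
#'
#' @param recon Continuous reconstruction volume (or an already-logical
#'   mask).
#' @param truth_mask Logical array (or numeric, thresholded at > 0).
#' @param threshold_frac Relative threshold in (0, 1); 0.5 = half-maximum.
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' # |A| = 120, |B| = 100, overlap 80: 160/220
#' a <- c(rep(TRUE, 120), rep(FALSE, 80))
#' b <- c(rep(TRUE, 80), rep(FALSE, 40), rep(TRUE, 20), rep(FALSE, 60))
#' dice(a, b)
#' @export
dice <- function(recon, truth_mask, threshold_frac = 0.5) {
  stop_if_not(length(recon) == length(truth_mask), "shape mismatch")
  stop_if_not(threshold_frac > 0 && threshold_frac < 1,
              "`threshold_frac` must be in (0, 1)")
  a <- if (is.logical(recon)) recon else {
    m <- max(recon)
    if (m > 0) recon >= threshold_frac * m else recon > 0
  }
  b <- if (is.logical(truth_mask)) truth_mask else truth_mask > 0
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    message("dice: both regions empty, defined as 1")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' Contrast-to-noise ratio
#'
#' `|mu_ROI - mu_BCK| / sqrt(w_ROI sigma2_ROI + w_BCK sigma2_BCK)` with
#' volume-proportional weights `w_ROI = |ROI| / (|ROI| + |BCK|)`,
#' `w_BCK = 1 - w_ROI`. Invariant to joint affine intensity changes.
#'
#' @param volume Numeric array.
#' @param roi_mask,bck_mask Disjoint non-empty logical arrays selecting the
#'   target and background regions.
#' @return CNR (non-negative; `Inf` with a warning when the pooled variance
#'   vanishes but the means differ).
#' @export
cnr <- function(volume, roi_mask, bck_mask) {
  stop_if_not(length(volume) == length(roi_mask) &&
                length(volume) == length(bck_mask), "shape mismatch")
  roi_mask <- as.logical(roi_mask); bck_mask <- as.logical(bck_mask)
  stop_if_not(any(roi_mask) && any(bck_mask), "masks must be non-empty")
  stop_if_not(!any(roi_mask & bck_mask), "masks must be disjoint")
  vr <- volume[roi_mask]; vb <- volume[bck_mask]
  mu_r <- mean(vr); mu_b <- mean(vb)
  # population variances (mean squared deviation)
  s2_r <- mean((vr - mu_r)^2); s2_b <- mean((vb - mu_b)^2)
  w_r <- length(vr) / (length(vr) + length(vb))
  pooled <- w_r * s2_r + (1 - w_r) * s2_b
  num <- abs(mu_r - mu_b)
  if (pooled <= 0) {
    if (num == 0) return(0)
    warning("zero pooled variance with unequal means: CNR is infinite")
    return(Inf)
  }
  num / sqrt(pooled)
}

#' Intensity profile along a line segment
#'
#' Trilinearly samples the max-normalized volume at `n_samples` points
#' between two voxel-space coordinates (1-based, continuous).
#'
#' @param volume 3D numeric array.
#' @param start,end Length-3 voxel coordinates inside the volume.
#' @param n_samples Number of samples (>= 2; the endpoints are included).
#' @return Object of class `profile_line`: data frame with the arc position
#'   `t` in `[0, 1]` and normalized `intensity`.
#' @export
intensity_profile <- function(volume, start, end, n_samples = 100) {
  stop_if_not(length(dim(volume)) == 3, "`volume` must be 3D")
  stop_if_not(n_samples >= 2, "need at least 2 samples")
  dims <- dim(volume)
  for (p in list(start, end)) {
    stop_if_not(length(p) == 3 && all(p >= 1) && all(p <= dims),
                "endpoints must lie inside the volume")
  }
  v <- normalize_volume(volume)
  tt <- seq(0, 1, length.out = n_samples)
  pts <- outer(tt, end - start) + rep(start, each = n_samples)
  vals <- trilinear_sample(v, pts)
  structure(data.frame(t = tt, intensity = vals),
            class = c("profile_line", "data.frame"))
}

trilinear_sample <- function(v, pts) {
  dims <- dim(v)
  i0 <- pmin(pmax(floor(pts), 1), rep(dims, each = nrow(pts)) - 1)
  fr <- pts - i0
  fr[fr < 0] <- 0; fr[fr > 1] <- 1
  out <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    out <- out + w * v[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  out
}

#' Label connected components of a 3D mask
#'
#' Breadth-first 6-connected labelling; used to check whether two targets
#' are resolved as separate components at half-maximum.
#'
#' @param mask Logical 3D array.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask) {
  stop_if_not(length(dim(mask)) == 3, "`mask` must be 3D")
  dims <- dim(mask)
  lab <- array(0L, dims)
  nvox <- prod(dims)
  offs <- c(-1L, 1L, -dims[1], dims[1], -dims[1] * dims[2], dims[1] * dims[2])
  ix <- arrayInd(seq_len(nvox), dims)
  cur <- 0L
  todo <- which(mask)
  seen <- logical(nvox)
  for (s in todo) {
    if (seen[s]) next
    cur <- cur + 1L
    frontier <- s
    seen[s] <- TRUE
    lab[s] <- cur
    while (length(frontier)) {
      nxt <- integer(0)
      for (k in seq_along(offs)) {
        cand <- frontier + offs[k]
        # reject neighbours that wrap across array edges
        ok <- cand >= 1 & cand <= nvox
        if (k <= 2) ok <- ok & (ix[frontier, 2] == ix[pmin(pmax(cand, 1), nvox), 2]) &
            (ix[frontier, 3] == ix[pmin(pmax(cand, 1), nvox), 3])
        if (k %in% 3:4) ok <- ok & (ix[frontier, 3] == ix[pmin(pmax(cand, 1), nvox), 3])
        cand <- cand[ok]
        cand <- cand[mask[cand] & !seen[cand]]
        if (length(cand)) {
          seen[cand] <- TRUE
          lab[cand] <- cur
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

#' Number of connected components at a relative threshold
#'
#' @param volume Continuous volume.
#' @param threshold_frac Relative threshold (0.5 = half-maximum).
#' @return Integer component count.
#' @export
count_components <- function(volume, threshold_frac = 0.5) {
  m <- max(volume)
  if (m <= 0) return(0L)
  max(label_components(volume >= threshold_frac * m))
}
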