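# Boundary-exitance projection onto the camera and measurement noise.
#
# The camera model is an orthographic splat: the exitance J = Phi/(2 kappa)
# at boundary nodes facing the camera is projected along the view direction
# onto the detector grid with bilinear weights and per-node boundary-area
# weighting. Free-space lens optics are deliberately not modelled.

#' Multi-view projection stack
#'
#' Container for a stack of detector images, one per view angle.
#'
#' @param images Numeric array `(n_views, n_u, n_v)`.
#' @param angles_deg View angles (degrees), one per image.
#' @return An object of class `projection_set`.
#' @export
projection_set <- function(images, angles_deg) {
  stop_if_not(is.array(images) && length(dim(images)) == 3,
              "`images` must be a 3D array (views, u, v)")
  stop_if_not(dim(images)[1] == length(angles_deg),
              "number of images and angles differ")
  stop_if_not(all(is.finite(images)), "projection values must be finite")
  structure(list(images = images, angles_deg = as.numeric(angles_deg)),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("projection_set: %d views of %d x %d (max %.4g)\n",
              d[1], d[2], d[3], max(x$images)))
  invisible(x)
}

# Sparse operator mapping boundary-node fluence to detector pixels for one
# view: rows are pixels (column-major over the n_u x n_v image), columns are
# boundary nodes. Includes visibility, bilinear splat weights, per-node
# boundary area, and the 1/(2 kappa) exitance factor.
projection_operator <- function(mesh, angle_deg, detector, kappa) {
  th <- angle_deg * pi / 180
  cam <- c(cos(th), sin(th), 0)
  bn <- mesh$boundary_nodes
  vis <- (mesh$node_normals %*% cam)[, 1] > 0
  npix <- detector$n_u * detector$n_v
  if (!any(vis)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(npix, length(bn))))
  }
  P <- mesh$nodes[bn[vis], , drop = FALSE]
  u <- -sin(th) * P[, 1] + cos(th) * P[, 2]
  v <- P[, 3]
  du <- detector$extent_cm / detector$n_u
  dv <- detector$extent_cm / detector$n_v
  fu <- u / du + detector$n_u / 2 + 0.5   # fractional pixel index
  fv <- v / dv + detector$n_v / 2 + 0.5
  iu0 <- floor(fu); iv0 <- floor(fv)
  wu <- fu - iu0; wv <- fv - iv0
  w_area <- mesh$node_boundary_areas[vis] / (2 * kappa)

  cols <- which(vis)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (su in 0:1) for (sv in 0:1) {
    pu <- iu0 + su; pv <- iv0 + sv
    w <- (if (su == 0) 1 - wu else wu) * (if (sv == 0) 1 - wv else wv) * w_area
    ok <- pu >= 1 & pu <= detector$n_u & pv >= 1 & pv <= detector$n_v & w > 0
    ii <- c(ii, (pv[ok] - 1L) * detector$n_u + pu[ok])
    jj <- c(jj, cols[ok])
    xx <- c(xx, w[ok])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(npix, length(bn)))
}

#' Project boundary fluence onto the detector for one view
#'
#' Computes the boundary exitance `J = Phi / (2 kappa)` at boundary nodes
#' whose outward normals face the camera, and splats it orthographically
#' (with bilinear weights and node-area weighting) onto the detector grid.
#' Back-facing nodes contribute nothing.
#'
#' @param fluence A [solve_fluence()] result (or numeric per-node vector).
#' @param mesh The `tet_mesh` the fluence lives on.
#' @param view_angle_deg View angle in degrees.
#' @param detector A [detector_model()].
#' @param kappa Boundary mismatch parameter (defaults to the mesh phantom's).
#' @return Numeric `n_u x n_v` detector image.
#' @export
boundary_projection <- function(fluence, mesh, view_angle_deg, detector,
                                kappa = mesh$phantom$optics$kappa) {
  stop_if_not(length(fluence) == nrow(mesh$nodes),
              "fluence must be nodal on the given mesh")
  P <- projection_operator(mesh, view_angle_deg %% 360, detector, kappa)
  img <- as.vector(P %*% as.numeric(fluence)[mesh$boundary_nodes])
  matrix(img, detector$n_u, detector$n_v)
}

#' Add white Gaussian measurement noise at a prescribed SNR
#'
#' Zero-mean i.i.d. Gaussian noise with standard deviation
#' `sigma = sqrt(mean(p^2) / 10^(snr_db/10))`, the SNR being defined over the
#' whole projection stack. `snr_db = Inf` returns the input unchanged.
#'
#' @param projections A [projection_set()].
#' @param snr_db Signal-to-noise ratio in dB (the noise-robustness sweeps use
#'   30, 25, 20 and 15 dB).
#' @param seed Optional integer seed for reproducible noise.
#' @return A noisy [projection_set()].
#' @export
add_gaussian_noise <- function(projections, snr_db, seed = NULL) {
  stop_if_not(inherits(projections, "projection_set"),
              "`projections` must be a projection_set")
  stop_if_not(is.numeric(snr_db) && length(snr_db) == 1 && !is.na(snr_db),
              "`snr_db` must be a single number (possibly Inf)")
  if (is.infinite(snr_db)) return(projections)
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- projections$images
  sigma <- sqrt(mean(p^2) / 10^(snr_db / 10))
  noisy <- p + array(stats::rnorm(length(p), 0, sigma), dim(p))
  projection_set(noisy, projections$angles_deg)
}

#' Write / read projection stacks as multi-page TIFF with a JSON sidecar
#'
#' One 32-bit float page per view; the view angles are stored next to the
#' TIFF in `<path>.angles.json`.
#'
#' @param projections A [projection_set()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_projections_tiff <- function(projections, path) {
  # TIFF stores [0,1]; keep the physical scale (and any negative noise
  # excursions) in the sidecar.
  lo <- min(projections$images, 0)
  hi <- max(projections$images)
  scale <- max(hi - lo, .Machine$double.xmin)
  imgs <- lapply(seq_len(dim(projections$images)[1]), function(v) {
    im <- (projections$images[v, , ] - lo) / scale
    t(im)[rev(seq_len(ncol(im))), , drop = FALSE]  # row-major display order
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(angles_deg = projections$angles_deg,
                            offset = lo, scale = scale),
                       paste0(path, ".angles.json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_projections_tiff
#' @export
read_projections_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(paste0(path, ".angles.json"),
                              simplifyVector = TRUE)
  n_v <- nrow(pages[[1]]); n_u <- ncol(pages[[1]])
  arr <- array(0, c(length(pages), n_u, n_v))
  for (v in seq_along(pages)) {
    arr[v, , ] <- t(pages[[v]][rev(seq_len(n_v)), , drop = FALSE]) *
      meta$scale + meta$offset
  }
  projection_set(arr, meta$angles_deg)
}
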