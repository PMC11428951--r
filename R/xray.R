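# Cone-beam X-ray excitation: source/detector descriptions and the
# Lambert-Beer intensity field inside the homogeneous cylinder phantom.

#' Cone-beam X-ray source
#'
#' The focal spot sits at `distance_cm` from the rotation axis at phantom
#' mid-height. The object rotates during the scan; in the phantom frame the
#' source (together with the camera) therefore rotates around the z axis.
#' Voltage and current are carried as metadata only; the beam is
#' monochromatic-equivalent with a single attenuation coefficient.
#'
#' @param distance_cm Source-to-axis distance (cm).
#' @param intensity Initial intensity X(r0), arbitrary units, positive.
#' @param voltage_kv,current_ma Metadata describing the tube setting.
#' @return An object of class `xray_source`.
#' @export
xray_source <- function(distance_cm = 20, intensity = 1,
                        voltage_kv = 40, current_ma = 1) {
  check_positive_scalar(distance_cm, "distance_cm")
  check_positive_scalar(intensity, "intensity")
  structure(list(distance_cm = distance_cm, intensity = intensity,
                 voltage_kv = voltage_kv, current_ma = current_ma),
            class = "xray_source")
}

#' Optical detector model
#'
#' Pixel grid, physical extent and view angles of the luminescence camera.
#' The default reproduces the full-scale acquisition: 24 views every 15
#' degrees over a full turn, 128 x 128 pixels.
#'
#' @param n_u,n_v Pixel counts (horizontal, vertical).
#' @param extent_cm Physical side length of the square detector (cm).
#' @param angles_deg View angles in degrees, strictly increasing in
#'   `[0, 360)`.
#' @return An object of class `detector_model`.
#' @export
detector_model <- function(n_u = 128, n_v = 128, extent_cm = 3.2,
                           angles_deg = seq(0, 345, by = 15)) {
  stop_if_not(n_u >= 1 && n_v >= 1, "pixel counts must be positive")
  check_positive_scalar(extent_cm, "extent_cm")
  stop_if_not(length(angles_deg) >= 1 && all(angles_deg >= 0) &&
                all(angles_deg < 360) && !is.unsorted(angles_deg, strictly = TRUE),
              "`angles_deg` must be strictly increasing in [0, 360)")
  structure(list(n_u = as.integer(n_u), n_v = as.integer(n_v),
                 extent_cm = extent_cm, angles_deg = as.numeric(angles_deg),
                 n_views = length(angles_deg)),
            class = "detector_model")
}

# Source focal position in the phantom frame at a given view angle. The
# camera looks along +d with d = (cos a, sin a, 0); the X-ray tube sits on
# the opposite side of the object so transmission illuminates the imaged face.
source_position <- function(source, angle_deg) {
  d <- c(cos(angle_deg * pi / 180), sin(angle_deg * pi / 180), 0)
  -source$distance_cm * d
}

#' X-ray intensity field inside the phantom
#'
#' Evaluates the Lambert-Beer attenuated cone-beam intensity
#' `X(p) = X(r0) * exp(-mu_t * L(p))` at interior points, where `L(p)` is the
#' length of the straight ray from the focal spot to `p` that lies inside the
#' cylinder (computed analytically for the homogeneous phantom).
#'
#' @param source An [xray_source()].
#' @param phantom A [cylinder_phantom()].
#' @param points_cm Numeric matrix (k x 3) of evaluation points (cm), inside
#'   or on the phantom.
#' @param angle_deg View angle (degrees); the focal spot rotates with the
#'   object frame.
#' @return Numeric vector of intensities at the points.
#' @export
xray_intensity_field <- function(source, phantom, points_cm, angle_deg = 0) {
  stop_if_not(inherits(source, "xray_source"), "`source` must be an xray_source")
  stop_if_not(inherits(phantom, "cylinder_phantom"), "`phantom` must be a cylinder_phantom")
  if (is.null(dim(points_cm))) points_cm <- matrix(points_cm, ncol = 3)
  R <- phantom$radius_cm; H <- phantom$height_cm
  tol <- 1e-9 + 1e-6 * R
  rad <- sqrt(points_cm[, 1]^2 + points_cm[, 2]^2)
  stop_if_not(all(rad <= R + tol) && all(abs(points_cm[, 3]) <= H / 2 + tol),
              "points must lie inside or on the phantom")
  f <- source_position(source, angle_deg)
  L <- ray_cylinder_path(f, points_cm, R, H)
  source$intensity * exp(-phantom$xray_mu_t * L)
}

# Length of the part of segment f -> p (parameter t in [0,1]) inside the
# finite cylinder x^2+y^2 <= R^2, |z| <= H/2. Vectorized over points.
ray_cylinder_path <- function(f, pts, R, H) {
  dx <- pts[, 1] - f[1]; dy <- pts[, 2] - f[2]; dz <- pts[, 3] - f[3]
  seg_len <- sqrt(dx^2 + dy^2 + dz^2)
  stop_if_not(all(seg_len > 0), "evaluation point coincides with the focal spot")

  # infinite cylinder: (f_xy + t d_xy)^2 = R^2
  a <- dx^2 + dy^2
  b <- 2 * (f[1] * dx + f[2] * dy)
  cc <- f[1]^2 + f[2]^2 - R^2
  disc <- b^2 - 4 * a * cc
  t0 <- rep(Inf, length(dx)); t1 <- rep(-Inf, length(dx))
  hit <- disc > 0 & a > 0
  sq <- sqrt(pmax(disc, 0))
  t0[hit] <- ((-b - sq) / (2 * a))[hit]
  t1[hit] <- ((-b + sq) / (2 * a))[hit]
  # vertical rays (a == 0): inside iff cc <= 0
  vert <- a <= .Machine$double.eps
  t0[vert & cc <= 0] <- -Inf
  t1[vert & cc <= 0] <- Inf

  # z slab
  z0 <- rep(-Inf, length(dz)); z1 <- rep(Inf, length(dz))
  mv <- abs(dz) > .Machine$double.eps
  za <- (-H / 2 - f[3]) / dz[mv]; zb <- (H / 2 - f[3]) / dz[mv]
  z0[mv] <- pmin(za, zb); z1[mv] <- pmax(za, zb)
  flat_out <- !mv & abs(f[3]) > H / 2
  z0[flat_out] <- Inf  # never inside

  tin <- pmax(pmax(t0, z0), 0)
  tout <- pmin(pmin(t1, z1), 1)
  pmax(tout - tin, 0) * seg_len
}
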