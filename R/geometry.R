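# Imaging object geometry: optical properties, the cylindrical phantom,
# luminescent targets, and the reconstruction voxel grid.
#
# Unit convention (fixed across the package): phantom dimensions, mesh node
# coordinates and all optical/FEM quantities are in centimetres; target
# geometry and the reconstruction grid are in millimetres. Conversions happen
# explicitly at module boundaries via mm_to_cm()/cm_to_mm().

#' Optical properties of a turbid medium
#'
#' Bundles the absorption coefficient, reduced scattering coefficient and the
#' boundary mismatch parameter of the Robin boundary condition, and derives
#' the diffusion coefficient `D = 1 / (3 * (mu_s_prime + mu_a))` used by the
#' diffusion approximation of light transport.
#'
#' @param mu_a Absorption coefficient (cm^-1), positive.
#' @param mu_s_prime Reduced scattering coefficient (cm^-1), positive.
#' @param kappa Boundary mismatch parameter (dimensionless), positive.
#'   `kappa = 1` corresponds to an index-matched boundary.
#' @return An object of class `optical_properties` with fields `mu_a`,
#'   `mu_s_prime`, `kappa`, and the derived diffusion coefficient `D` (cm).
#' @examples
#' op <- optical_properties(mu_a = 0.02, mu_s_prime = 10)
#' op$D  # 1 / (3 * 10.02)
#' @export
optical_properties <- function(mu_a, mu_s_prime, kappa = 1) {
  check_positive_scalar(mu_a, "mu_a")
  check_positive_scalar(mu_s_prime, "mu_s_prime")
  check_positive_scalar(kappa, "kappa")
  structure(
    list(mu_a = mu_a, mu_s_prime = mu_s_prime, kappa = kappa,
         D = 1 / (3 * (mu_s_prime + mu_a))),
    class = "optical_properties"
  )
}

#' Cylindrical imaging phantom
#'
#' Defines the homogeneous cylindrical object in which luminescent targets are
#' embedded. The cylinder axis is the z axis and the origin sits on the axis
#' at mid-height.
#'
#' @param diameter_cm,height_cm Cylinder dimensions in cm, positive.
#' @param optics An [optical_properties()] object.
#' @param xray_mu_t Homogeneous X-ray attenuation coefficient (cm^-1,
#'   non-negative). The absolute value only rescales the simulated signal,
#'   which cancels under max-normalization of reconstructions.
#' @return An object of class `cylinder_phantom`.
#' @examples
#' ph <- cylinder_phantom(3.0, 2.3, optical_properties(0.02, 10))
#' @export
cylinder_phantom <- function(diameter_cm, height_cm, optics,
                             xray_mu_t = 0.3) {
  check_positive_scalar(diameter_cm, "diameter_cm")
  check_positive_scalar(height_cm, "height_cm")
  stop_if_not(inherits(optics, "optical_properties"),
              "`optics` must be created by optical_properties()")
  stop_if_not(is_scalar_num(xray_mu_t) && xray_mu_t >= 0,
              "`xray_mu_t` must be a single non-negative number")
  structure(
    list(diameter_cm = diameter_cm, height_cm = height_cm,
         radius_cm = diameter_cm / 2, optics = optics,
         xray_mu_t = xray_mu_t),
    class = "cylinder_phantom"
  )
}

#' @export
print.cylinder_phantom <- function(x, ...) {
  cat(sprintf("cylinder phantom: %.2f cm diameter x %.2f cm height\n",
              x$diameter_cm, x$height_cm))
  cat(sprintf("  mu_a = %g cm^-1, mu_s' = %g cm^-1, D = %.5f cm, kappa = %g\n",
              x$optics$mu_a, x$optics$mu_s_prime, x$optics$D, x$optics$kappa))
  cat(sprintf("  X-ray mu_t = %g cm^-1\n", x$xray_mu_t))
  invisible(x)
}

#' Reconstruction voxel grid
#'
#' Regular grid on which nanoparticle concentration is reconstructed. The
#' in-plane extent covers the phantom diameter; the z band of `nz` slices with
#' spacing `z_spacing_mm` is centred on the phantom mid-height (`z_center_mm`
#' shifts it).
#'
#' @param nx,ny,nz Grid shape. The full-scale configuration is 128 x 128 x 7.
#' @param diameter_mm In-plane physical extent (mm); spacing is
#'   `diameter_mm / nx`.
#' @param z_spacing_mm Slice spacing in mm (1 mm at full scale).
#' @param z_center_mm Centre of the z band, mm.
#' @return An object of class `voxel_grid` with voxel-centre coordinate
#'   vectors `x_mm`, `y_mm`, `z_mm`.
#' @export
voxel_grid <- function(nx = 128, ny = 128, nz = 7, diameter_mm = 30,
                       z_spacing_mm = 1, z_center_mm = 0) {
  stop_if_not(nx >= 1 && ny >= 1 && nz >= 1, "grid shape must be positive")
  check_positive_scalar(diameter_mm, "diameter_mm")
  check_positive_scalar(z_spacing_mm, "z_spacing_mm")
  dx <- diameter_mm / nx
  dy <- diameter_mm / ny
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
         diameter_mm = diameter_mm,
         dx_mm = dx, dy_mm = dy, dz_mm = z_spacing_mm,
         x_mm = (seq_len(nx) - (nx + 1) / 2) * dx,
         y_mm = (seq_len(ny) - (ny + 1) / 2) * dy,
         z_mm = (seq_len(nz) - (nz + 1) / 2) * z_spacing_mm + z_center_mm),
    class = "voxel_grid"
  )
}

#' Cylindrical luminescent target
#'
#' An axis-aligned cylinder of nanophosphor (e.g. Y2O3:Eu3+) embedded in the
#' phantom.
#'
#' @param center_mm Numeric length-3, target centre (x, y, z) in mm,
#'   phantom-centred coordinates.
#' @param diameter_mm,height_mm Target dimensions in mm.
#' @param concentration Nanoparticle concentration (mg/mL), non-negative.
#' @param light_yield Photons emitted per unit concentration per unit X-ray
#'   intensity (arbitrary units), positive.
#' @return An object of class `xlct_target`.
#' @export
xlct_target <- function(center_mm, diameter_mm = 4, height_mm = 4,
                        concentration = 50, light_yield = 1) {
  stop_if_not(is.numeric(center_mm) && length(center_mm) == 3 &&
                all(is.finite(center_mm)), "`center_mm` must be numeric length 3")
  check_positive_scalar(diameter_mm, "diameter_mm")
  check_positive_scalar(height_mm, "height_mm")
  stop_if_not(is_scalar_num(concentration) && concentration >= 0,
              "`concentration` must be a single non-negative number")
  check_positive_scalar(light_yield, "light_yield")
  structure(
    list(center_mm = as.numeric(center_mm), diameter_mm = diameter_mm,
         radius_mm = diameter_mm / 2, height_mm = height_mm,
         concentration = concentration, light_yield = light_yield),
    class = "xlct_target"
  )
}

target_inside_phantom <- function(target, phantom, strict_margin_mm = 0) {
  r_ph <- cm_to_mm(phantom$radius_cm)
  h_ph <- cm_to_mm(phantom$height_cm)
  rad_ok <- sqrt(sum(target$center_mm[1:2]^2)) + target$radius_mm <
    r_ph - strict_margin_mm
  z_ok <- abs(target$center_mm[3]) + target$height_mm / 2 <
    h_ph / 2 - strict_margin_mm
  rad_ok && z_ok
}

#' Edge-to-edge distance between two cylindrical targets
#'
#' In-plane distance between the cylinder surfaces (both targets are
#' z-axis-aligned): centre distance in the xy plane minus both radii. A
#' negative value signals overlapping targets.
#'
#' @param t1,t2 [xlct_target()] objects.
#' @return The edge-to-edge distance in mm (possibly negative).
#' @examples
#' a <- xlct_target(c(-3, 0, 0), diameter_mm = 4)
#' b <- xlct_target(c(3, 0, 0), diameter_mm = 4)
#' compute_eed(a, b)  # 6 - 2 - 2 = 2
#' @export
compute_eed <- function(t1, t2) {
  stop_if_not(inherits(t1, "xlct_target") && inherits(t2, "xlct_target"),
              "inputs must be xlct_target objects")
  d <- sqrt(sum((t1$center_mm[1:2] - t2$center_mm[1:2])^2))
  d - t1$radius_mm - t2$radius_mm
}

#' Randomly place luminescent targets inside the phantom
#'
#' Rejection-samples `n_targets` cylindrical targets whose centres fall in the
#' square `|x|,|y| <= center_range_mm`, that lie strictly inside the phantom,
#' and whose pairwise edge-to-edge distances all fall within `eed_range_mm`
#' (the training-set recipe uses 0.3 to 2.5 mm). For two targets the whole
#' configuration is redrawn on rejection so the accepted centre distribution
#' is uniform conditioned on the constraints; for three targets later targets
#' are proposed in the feasible annulus of a random earlier target and all
#' pairwise constraints are re-checked.
#'
#' @param phantom A [cylinder_phantom()].
#' @param n_targets 2 or 3.
#' @param diam_choices_mm Diameters sampled uniformly per target (mm).
#' @param height_mm Target height (mm).
#' @param center_range_mm Half-width of the centre sampling square (mm).
#' @param eed_range_mm Length-2 inclusive interval for every pairwise
#'   edge-to-edge distance (mm); must be non-negative and increasing.
#' @param concentration Concentration assigned to every target (mg/mL).
#' @param z_jitter_mm Targets sit at mid-height with a uniform z jitter of
#'   plus/minus this amount (mm).
#' @param seed Integer seed; the draw is bit-reproducible for a fixed seed.
#' @param max_attempts Rejection-sampling budget; exceeding it is an error,
#'   constraints are never silently relaxed.
#' @return A list of [xlct_target()] objects.
#' @export
sample_targets <- function(phantom, n_targets = 2, diam_choices_mm = c(3, 4),
                           height_mm = 4, center_range_mm = 10,
                           eed_range_mm = c(0.3, 2.5), concentration = 50,
                           z_jitter_mm = 1, seed = NULL,
                           max_attempts = 10000) {
  stop_if_not(n_targets %in% c(2L, 3L), "`n_targets` must be 2 or 3")
  stop_if_not(is.numeric(eed_range_mm) && length(eed_range_mm) == 2 &&
                eed_range_mm[1] >= 0 && eed_range_mm[2] > eed_range_mm[1],
              "`eed_range_mm` must be an increasing non-negative interval")
  check_positive_scalar(center_range_mm, "center_range_mm")
  if (!is.null(seed)) set.seed(as.integer(seed))

  draw_one <- function() {
    xlct_target(
      center_mm = c(stats::runif(2, -center_range_mm, center_range_mm),
                    stats::runif(1, -z_jitter_mm, z_jitter_mm)),
      diameter_mm = sample(rep(diam_choices_mm, 2), 1),
      height_mm = height_mm, concentration = concentration
    )
  }
  target_ok <- function(tg) {
    target_inside_phantom(tg, phantom) &&
      all(abs(tg$center_mm[1:2]) <= center_range_mm)
  }
  eeds_ok <- function(tgs) {
    if (length(tgs) < 2) return(TRUE)
    prs <- utils::combn(length(tgs), 2)
    all(apply(prs, 2, function(p) {
      e <- compute_eed(tgs[[p[1]]], tgs[[p[2]]])
      e >= eed_range_mm[1] && e <= eed_range_mm[2]
    }))
  }

  attempts <- 0
  if (n_targets == 2L) {
    repeat {
      attempts <- attempts + 1
      if (attempts > max_attempts)
        stop("target placement failed: rejection budget exhausted", call. = FALSE)
      tgs <- list(draw_one(), draw_one())
      if (all(vapply(tgs, target_ok, logical(1))) && eeds_ok(tgs)) return(tgs)
    }
  }
  # Three targets: anchor-annulus proposals keep the rejection rate workable.
  repeat {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop("target placement failed: rejection budget exhausted", call. = FALSE)
    tgs <- list(draw_one())
    if (!target_ok(tgs[[1]])) next
    ok <- TRUE
    for (k in 2:n_targets) {
      anchor <- tgs[[sample.int(length(tgs), 1)]]
      diam <- sample(rep(diam_choices_mm, 2), 1)
      gap <- stats::runif(1, eed_range_mm[1], eed_range_mm[2])
      dist <- anchor$radius_mm + diam / 2 + gap
      ang <- stats::runif(1, 0, 2 * pi)
      cand <- xlct_target(
        center_mm = c(anchor$center_mm[1:2] + dist * c(cos(ang), sin(ang)),
                      stats::runif(1, -z_jitter_mm, z_jitter_mm)),
        diameter_mm = diam, height_mm = height_mm,
        concentration = concentration
      )
      if (!target_ok(cand)) { ok <- FALSE; break }
      tgs <- c(tgs, list(cand))
      if (!eeds_ok(tgs)) { ok <- FALSE; break }
    }
    if (ok) return(tgs)
  }
}

#' Rasterize targets onto the voxel grid
#'
#' Produces the ground-truth concentration volume (voxel centres falling
#' inside any target take that target's concentration) and a region-of-
#' interest mask formed by the union of per-target axis-aligned bounding
#' boxes dilated by `roi_margin` voxels.
#'
#' @param targets List of [xlct_target()] objects (possibly empty).
#' @param grid A [voxel_grid()].
#' @param roi_margin Dilation margin of the bounding boxes, in voxels.
#' @return List with `truth` (numeric nx x ny x nz array, mg/mL) and
#'   `roi_mask` (logical array of the same shape).
#' @export
rasterize_targets <- function(targets, grid, roi_margin = 1) {
  stop_if_not(inherits(grid, "voxel_grid"), "`grid` must be a voxel_grid")
  dims <- c(grid$nx, grid$ny, grid$nz)
  truth <- array(0, dims)
  roi <- array(FALSE, dims)
  if (length(targets) == 0) return(list(truth = truth, roi_mask = roi))
  for (tg in targets) {
    stop_if_not(inherits(tg, "xlct_target"), "targets must be xlct_target objects")
    inx <- abs(grid$x_mm - tg$center_mm[1]) <= tg$radius_mm
    iny <- abs(grid$y_mm - tg$center_mm[2]) <= tg$radius_mm
    inz <- abs(grid$z_mm - tg$center_mm[3]) <= tg$height_mm / 2
    ix <- which(inx); iy <- which(iny); iz <- which(inz)
    if (!length(ix) || !length(iy) || !length(iz)) next
    # exact in-cylinder test on the candidate box
    dx2 <- outer((grid$x_mm[ix] - tg$center_mm[1])^2,
                 (grid$y_mm[iy] - tg$center_mm[2])^2, "+")
    inside <- dx2 <= tg$radius_mm^2
    for (k in iz) {
      sl <- truth[ix, iy, k, drop = FALSE]
      sl <- array(sl, dim(inside))
      sl[inside] <- pmax(sl[inside], tg$concentration)
      truth[ix, iy, k] <- sl
    }
    bx <- pmax(1, min(ix) - roi_margin):pmin(dims[1], max(ix) + roi_margin)
    by <- pmax(1, min(iy) - roi_margin):pmin(dims[2], max(iy) + roi_margin)
    bz <- pmax(1, min(iz) - roi_margin):pmin(dims[3], max(iz) + roi_margin)
    roi[bx, by, bz] <- TRUE
  }
  list(truth = truth, roi_mask = roi)
}

# Logical mask of in-plane voxels lying inside the phantom cross-section,
# replicated across slices. Used to restrict reconstruction to the object.
phantom_voxel_mask <- function(phantom, grid) {
  r_mm <- cm_to_mm(phantom$radius_cm)
  inplane <- outer(grid$x_mm^2, grid$y_mm^2, "+") <= r_mm^2
  array(rep(inplane, grid$nz), c(grid$nx, grid$ny, grid$nz))
}
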