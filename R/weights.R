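# Weight-matrix assembly and full forward simulation.
#
# The discrete forward model is y = W x: x holds nanoparticle concentration
# on the in-phantom voxels of the reconstruction grid, y stacks all detector
# pixels view-major (view 1 pixels first, column-major within each image).
# Column j of W is the full physics chain (X-ray excitation of a unit
# concentration in voxel j -> FEM diffusion solve -> boundary exitance splat)
# for every view. Two assembly routes are provided and must agree: a direct
# route (one diffusion solve per voxel) and an adjoint/reciprocity route (one
# solve per boundary node, exploiting the symmetry of the FEM system), which
# is much cheaper whenever the boundary is smaller than the voxel set.

# Midpoint-quadrature source basis: sparse matrix B0 (n_nodes x n_voxels)
# with column j holding vol_j * phi_i(c_j) for the four P1 basis functions of
# the tetrahedron containing voxel centre c_j. Voxel centres outside the
# meshed cylinder are dropped; the surviving linear grid indices are returned.
build_source_basis <- function(mesh, grid) {
  stop_if_not(inherits(mesh, "tet_mesh"), "`mesh` must be a tet_mesh")
  stop_if_not(inherits(grid, "voxel_grid"), "`grid` must be a voxel_grid")
  cx <- mm_to_cm(grid$x_mm); cy <- mm_to_cm(grid$y_mm); cz <- mm_to_cm(grid$z_mm)
  vol_cm3 <- mm_to_cm(grid$dx_mm) * mm_to_cm(grid$dy_mm) * mm_to_cm(grid$dz_mm)
  nvox_all <- grid$nx * grid$ny * grid$nz

  assigned <- logical(nvox_all)
  vox_id <- integer(0); node_id <- integer(0); wt <- numeric(0)

  tets <- mesh$tets
  nodes <- mesh$nodes
  p1 <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4], , drop = FALSE] - p1
  # rows of inv(J) for barycentric coordinates: lambda_{2..4} = inv(J) (p-p1)
  det6 <- 6 * mesh$volumes
  inv_rows <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1]) / det6
  }
  r1 <- inv_rows(e2, e3); r2 <- inv_rows(e3, e1); r3 <- inv_rows(e1, e2)

  tol <- -1e-9
  for (tt in seq_len(nrow(tets))) {
    vix <- which(cx >= min(p1[tt, 1], p1[tt, 1] + e1[tt, 1], p1[tt, 1] + e2[tt, 1], p1[tt, 1] + e3[tt, 1]) - 1e-12 &
                   cx <= max(p1[tt, 1], p1[tt, 1] + e1[tt, 1], p1[tt, 1] + e2[tt, 1], p1[tt, 1] + e3[tt, 1]) + 1e-12)
    if (!length(vix)) next
    viy <- which(cy >= min(p1[tt, 2], p1[tt, 2] + e1[tt, 2], p1[tt, 2] + e2[tt, 2], p1[tt, 2] + e3[tt, 2]) - 1e-12 &
                   cy <= max(p1[tt, 2], p1[tt, 2] + e1[tt, 2], p1[tt, 2] + e2[tt, 2], p1[tt, 2] + e3[tt, 2]) + 1e-12)
    if (!length(viy)) next
    viz <- which(cz >= min(p1[tt, 3], p1[tt, 3] + e1[tt, 3], p1[tt, 3] + e2[tt, 3], p1[tt, 3] + e3[tt, 3]) - 1e-12 &
                   cz <= max(p1[tt, 3], p1[tt, 3] + e1[tt, 3], p1[tt, 3] + e2[tt, 3], p1[tt, 3] + e3[tt, 3]) + 1e-12)
    if (!length(viz)) next
    cand <- expand.grid(ix = vix, iy = viy, iz = viz)
    lin <- cand$ix + (cand$iy - 1L) * grid$nx +
      (cand$iz - 1L) * grid$nx * grid$ny
    keep <- !assigned[lin]
    if (!any(keep)) next
    cand <- cand[keep, , drop = FALSE]; lin <- lin[keep]
    dp <- cbind(cx[cand$ix] - p1[tt, 1], cy[cand$iy] - p1[tt, 2],
                cz[cand$iz] - p1[tt, 3])
    l2 <- dp %*% r1[tt, ]; l3 <- dp %*% r2[tt, ]; l4 <- dp %*% r3[tt, ]
    l1 <- 1 - l2 - l3 - l4
    inside <- l1 >= tol & l2 >= tol & l3 >= tol & l4 >= tol
    if (!any(inside)) next
    lin <- lin[inside]
    lam <- cbind(l1[inside], l2[inside], l3[inside], l4[inside])
    assigned[lin] <- TRUE
    vox_id <- c(vox_id, rep(lin, 4L))
    node_id <- c(node_id, rep(tets[tt, ], each = length(lin)))
    wt <- c(wt, as.vector(lam) * vol_cm3)
  }
  voxel_idx <- which(assigned)
  col <- match(vox_id, voxel_idx)
  B0 <- Matrix::sparseMatrix(i = node_id, j = col, x = wt,
                             dims = c(nrow(nodes), length(voxel_idx)))
  centers <- cbind(cx[((voxel_idx - 1L) %% grid$nx) + 1L],
                   cy[(((voxel_idx - 1L) %/% grid$nx) %% grid$ny) + 1L],
                   cz[((voxel_idx - 1L) %/% (grid$nx * grid$ny)) + 1L])
  list(B0 = B0, voxel_idx = voxel_idx, centers_cm = centers)
}

# X-ray intensity at the retained voxel centres, one column per view.
voxel_xray_intensity <- function(source, phantom, centers_cm, angles_deg) {
  vapply(angles_deg, function(a) {
    xray_intensity_field(source, phantom, centers_cm, a)
  }, numeric(nrow(centers_cm)))
}

#' Assemble the CB-XLCT weight matrix
#'
#' Builds the dense linear operator from in-phantom voxel concentrations to
#' the stacked multi-view detector measurement. `method = "adjoint"` performs
#' one Cholesky back-solve per boundary node and exploits the symmetry of the
#' FEM system (reciprocity); `method = "direct"` performs one solve per voxel
#' and exists as the independently-ordered reference route. Both produce the
#' same matrix to solver precision.
#'
#' @param mesh A [mesh_cylinder()] mesh of the phantom.
#' @param grid A [voxel_grid()].
#' @param detector A [detector_model()].
#' @param source An [xray_source()].
#' @param gamma Light yield of the nanophosphor (scales all entries).
#' @param method `"adjoint"` or `"direct"`.
#' @param system Optionally a pre-assembled [assemble_diffusion_system()].
#' @return An object of class `weight_matrix`: dense matrix `W`
#'   (`n_views * n_u * n_v` rows, one column per retained voxel), the linear
#'   `voxel_idx` into the grid, and the grid/detector descriptions.
#' @export
build_weight_matrix <- function(mesh, grid, detector, source, gamma = 1,
                                method = c("adjoint", "direct"),
                                system = NULL) {
  method <- match.arg(method)
  phantom <- mesh$phantom
  if (is.null(system)) {
    system <- assemble_diffusion_system(mesh, phantom$optics,
                                        scheme = "monotone")
  }
  sb <- build_source_basis(mesh, grid)
  X <- voxel_xray_intensity(source, phantom, sb$centers_cm, detector$angles_deg)
  kappa <- phantom$optics$kappa
  bn <- mesh$boundary_nodes
  n <- nrow(mesh$nodes)
  npix <- detector$n_u * detector$n_v
  nvox <- length(sb$voxel_idx)
  W <- matrix(0, npix * detector$n_views, nvox)

  if (method == "adjoint") {
    E <- Matrix::sparseMatrix(i = bn, j = seq_along(bn),
                              x = rep(1, length(bn)), dims = c(n, length(bn)))
    G <- as.matrix(Matrix::solve(system_cholesky(system), E))  # n x n_bnd
    K0 <- as.matrix(Matrix::crossprod(G, sb$B0))               # n_bnd x nvox
    for (v in seq_len(detector$n_views)) {
      P <- projection_operator(mesh, detector$angles_deg[v], detector, kappa)
      Wv <- as.matrix(P %*% (K0 * rep(X[, v], each = nrow(K0))))
      W[((v - 1L) * npix + 1L):(v * npix), ] <- gamma * Wv
    }
  } else {
    Phi <- as.matrix(Matrix::solve(system_cholesky(system), sb$B0))  # n x nvox
    Phib <- Phi[bn, , drop = FALSE]
    for (v in seq_len(detector$n_views)) {
      P <- projection_operator(mesh, detector$angles_deg[v], detector, kappa)
      Wv <- as.matrix(P %*% Phib) * rep(X[, v], each = npix)
      W[((v - 1L) * npix + 1L):(v * npix), ] <- gamma * Wv
    }
  }
  stop_if_not(all(is.finite(W)) && min(W) >= 0,
              "weight matrix entries must be finite and non-negative")
  structure(list(W = W, voxel_idx = sb$voxel_idx, grid = grid,
                 detector = detector, gamma = gamma, method = method),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("weight_matrix: %d measurements x %d voxels (%s assembly)\n",
              nrow(x$W), ncol(x$W), x$method))
  invisible(x)
}

# Restrict a full-grid volume to the weight matrix's voxel vector (and back).
volume_to_coeffs <- function(wm, volume) {
  stop_if_not(all(dim(volume) == c(wm$grid$nx, wm$grid$ny, wm$grid$nz)),
              "volume shape does not match the grid")
  as.numeric(volume)[wm$voxel_idx]
}

coeffs_to_volume <- function(wm, x) {
  v <- numeric(wm$grid$nx * wm$grid$ny * wm$grid$nz)
  v[wm$voxel_idx] <- x
  array(v, c(wm$grid$nx, wm$grid$ny, wm$grid$nz))
}

#' Apply the weight matrix to a concentration volume
#'
#' @param wm A [build_weight_matrix()] result.
#' @param volume Full-grid concentration array (or a coefficient vector over
#'   `wm$voxel_idx`).
#' @return A [projection_set()].
#' @export
project_volume <- function(wm, volume) {
  x <- if (is.array(volume) && length(dim(volume)) == 3) {
    volume_to_coeffs(wm, volume)
  } else as.numeric(volume)
  stop_if_not(length(x) == ncol(wm$W), "dimension mismatch")
  y <- wm$W %*% x
  det <- wm$detector
  projection_set(array(y, c(det$n_u, det$n_v, det$n_views)) |>
                   aperm(c(3, 1, 2)),
                 det$angles_deg)
}

# Stack a projection_set into the measurement vector ordering of W.
stack_measurements <- function(projections) {
  as.vector(aperm(projections$images, c(2, 3, 1)))
}

#' Simulate noise-free multi-view projections of luminescent targets
#'
#' Runs the full forward chain per view: rasterize the targets, excite with
#' the rotating cone-beam X-ray field, solve the FEM diffusion equation for
#' the emitted light, and splat the boundary exitance onto the camera. No
#' weight matrix is involved; this is the reference forward route.
#'
#' @param phantom A [cylinder_phantom()].
#' @param targets List of [xlct_target()]s (may be empty).
#' @param detector A [detector_model()].
#' @param source An [xray_source()].
#' @param mesh Optional pre-built mesh (default: edge = radius/6).
#' @param grid Optional [voxel_grid()] carrying the rasterization resolution.
#' @param gamma Light yield.
#' @param system Optional pre-assembled diffusion system.
#' @return A [projection_set()] of `n_views` noise-free images.
#' @export
simulate_projections <- function(phantom, targets, detector, source,
                                 mesh = NULL, grid = NULL, gamma = 1,
                                 system = NULL) {
  if (is.null(mesh)) mesh <- mesh_cylinder(phantom, phantom$radius_cm / 6)
  if (is.null(grid)) {
    grid <- voxel_grid(nx = 48, ny = 48, nz = 5,
                       diameter_mm = cm_to_mm(phantom$diameter_cm))
  }
  if (is.null(system)) {
    system <- assemble_diffusion_system(mesh, phantom$optics,
                                        scheme = "monotone")
  }
  ras <- rasterize_targets(targets, grid)
  sb <- build_source_basis(mesh, grid)
  n_coef <- as.numeric(ras$truth)[sb$voxel_idx]
  det <- detector
  imgs <- array(0, c(det$n_views, det$n_u, det$n_v))
  if (any(n_coef > 0)) {
    X <- voxel_xray_intensity(source, phantom, sb$centers_cm, det$angles_deg)
    for (v in seq_len(det$n_views)) {
      load <- as.vector(sb$B0 %*% (gamma * n_coef * X[, v]))
      phi <- solve_fluence(system, rhs = load)
      imgs[v, , ] <- boundary_projection(phi, mesh, det$angles_deg[v], det)
    }
  }
  projection_set(imgs, det$angles_deg)
}
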