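# Structured tetrahedral meshing of the cylinder phantom.
#
# The disk cross-section is triangulated by mapping a regular (2m+1)^2 grid on
# the unit square onto the disk with the concentric-square (Shirley-Chiu
# style) map, which keeps square contour levels on circles and yields a valid
# triangulation with trivially known connectivity. The triangulated disk is
# extruded into prism layers along z; every prism is split into three
# tetrahedra using the sorted-global-index rule, which guarantees that the
# diagonals of shared quadrilateral faces agree between neighbouring prisms,
# so the mesh is conforming and watertight by construction.

#' Tetrahedral mesh of a cylinder phantom
#'
#' @param phantom A [cylinder_phantom()].
#' @param target_edge_cm Requested edge length (cm); must satisfy
#'   `0 < target_edge_cm < diameter/4`. Node count grows as the edge shrinks.
#' @return An object of class `tet_mesh` with fields `nodes` (n x 3, cm),
#'   `tets` (m x 4 node indices, positively oriented), `volumes` (cm^3),
#'   `boundary_faces` (f x 3), `boundary_normals` (outward unit normals),
#'   `boundary_areas` (cm^2), `boundary_nodes`, `node_normals` and
#'   `node_boundary_areas` (per-boundary-node area weights).
#' @export
mesh_cylinder <- function(phantom, target_edge_cm) {
  stop_if_not(inherits(phantom, "cylinder_phantom"), "`phantom` must be a cylinder_phantom")
  stop_if_not(is_scalar_num(target_edge_cm) && target_edge_cm > 0 &&
                target_edge_cm < phantom$diameter_cm / 4,
              "`target_edge_cm` must satisfy 0 < edge < diameter/4")
  R <- phantom$radius_cm
  H <- phantom$height_cm
  m <- max(2L, as.integer(ceiling(R / target_edge_cm)))
  nlay <- max(2L, as.integer(ceiling(H / target_edge_cm)))

  # --- 2D disk nodes via concentric-square map ---
  s <- seq(-1, 1, length.out = 2L * m + 1L)
  gr <- expand.grid(a = s, b = s)
  a <- gr$a; b <- gr$b
  t_lvl <- pmax(abs(a), abs(b))
  nrm <- sqrt(a^2 + b^2)
  scl <- ifelse(nrm > 0, t_lvl / nrm, 0)
  x2 <- a * scl * R
  y2 <- b * scl * R
  n2 <- length(x2)
  side <- 2L * m + 1L
  vid <- function(i, j) (j - 1L) * side + i   # i = a-index, j = b-index

  # two triangles per grid cell
  i <- rep(seq_len(side - 1L), side - 1L)
  j <- rep(seq_len(side - 1L), each = side - 1L)
  v00 <- vid(i, j); v10 <- vid(i + 1L, j)
  v01 <- vid(i, j + 1L); v11 <- vid(i + 1L, j + 1L)
  tris <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))

  # drop zero-area triangles (the square->disk map collapses none, but guard)
  ax <- x2[tris[, 2]] - x2[tris[, 1]]; ay <- y2[tris[, 2]] - y2[tris[, 1]]
  bx <- x2[tris[, 3]] - x2[tris[, 1]]; by <- y2[tris[, 3]] - y2[tris[, 1]]
  area2 <- ax * by - ay * bx
  stop_if_not(all(abs(area2) > 1e-14), "degenerate triangles in disk mesh")
  tris[area2 < 0, ] <- tris[area2 < 0, c(1, 3, 2)]  # consistent orientation

  # --- extrude to layers ---
  z <- seq(-H / 2, H / 2, length.out = nlay + 1L)
  nodes <- cbind(rep(x2, nlay + 1L), rep(y2, nlay + 1L),
                 rep(z, each = n2))

  # prism split by sorted-index rule: for sorted triangle (a < b < c) with top
  # copies a', b', c' (offset +n2), tets are (a,b,c,c'), (a,b,c',b'), (a,b',c',a')
  tris_sorted <- t(apply(tris, 1, sort))
  ntri <- nrow(tris_sorted)
  tets_list <- vector("list", nlay)
  for (l in seq_len(nlay)) {
    off <- (l - 1L) * n2
    A <- tris_sorted[, 1] + off; B <- tris_sorted[, 2] + off; C <- tris_sorted[, 3] + off
    At <- A + n2; Bt <- B + n2; Ct <- C + n2
    tets_list[[l]] <- rbind(cbind(A, B, C, Ct),
                            cbind(A, B, Ct, Bt),
                            cbind(A, Bt, Ct, At))
  }
  tets <- do.call(rbind, tets_list)

  vol <- tet_volumes(nodes, tets)
  neg <- vol < 0
  if (any(neg)) {  # fix orientation by swapping last two nodes
    tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
    vol <- abs(vol)
  }
  stop_if_not(all(vol > 1e-12), "meshing error: degenerate tetrahedra")

  bf <- extract_boundary_faces(nodes, tets)

  structure(
    c(list(nodes = nodes, tets = tets, volumes = vol,
           target_edge_cm = target_edge_cm, phantom = phantom),
      bf),
    class = "tet_mesh"
  )
}

# Signed volumes of tetrahedra (vectorized).
tet_volumes <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4], , drop = FALSE] - p1
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
    e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
    e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
}

# Boundary faces are those shared by exactly one tetrahedron. Faces are keyed
# by their sorted node triple packed into a double (safe below ~2e5 nodes).
extract_boundary_faces <- function(nodes, tets) {
  nt <- nrow(tets)
  faces <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
                 tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  owner <- rep(seq_len(nt), 4L)
  f1 <- pmin(faces[, 1], faces[, 2], faces[, 3])
  f3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
  f2 <- faces[, 1] + faces[, 2] + faces[, 3] - f1 - f3
  fs <- cbind(f1, f2, f3)
  nn <- nrow(nodes)
  stop_if_not(nn^3 < 2^53, "mesh too large for face keying")
  key <- (as.numeric(f1) * nn + f2) * nn + f3
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  stop_if_not(!any(duplicated(key[duplicated(key)])), "mesh is not manifold")
  is_bnd <- !dup
  bfaces <- fs[is_bnd, , drop = FALSE]
  bowner <- owner[is_bnd]

  p1 <- nodes[bfaces[, 1], , drop = FALSE]
  e1 <- nodes[bfaces[, 2], , drop = FALSE] - p1
  e2 <- nodes[bfaces[, 3], , drop = FALSE] - p1
  nrml <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  areas <- sqrt(rowSums(nrml^2)) / 2
  nrml <- nrml / (2 * areas)
  # orient outward: away from the owning tet's centroid
  tc <- (nodes[tets[bowner, 1], ] + nodes[tets[bowner, 2], ] +
           nodes[tets[bowner, 3], ] + nodes[tets[bowner, 4], ]) / 4
  fc <- (p1 + nodes[bfaces[, 2], ] + nodes[bfaces[, 3], ]) / 3
  flip <- rowSums(nrml * (fc - tc)) < 0
  nrml[flip, ] <- -nrml[flip, ]

  bnodes <- sort(unique(as.vector(bfaces)))
  # area-weighted node normals and per-node boundary area (1/3 of each face)
  nn_acc <- matrix(0, length(bnodes), 3)
  na_acc <- numeric(length(bnodes))
  pos <- match(as.vector(bfaces), bnodes)
  w <- rep(areas / 3, 3L)
  for (d in 1:3) {
    nn_acc[, d] <- as.vector(rowsum(w * rep(nrml[, d], 3L), pos,
                                    reorder = TRUE))
  }
  na_acc <- as.vector(rowsum(w, pos, reorder = TRUE))
  len <- sqrt(rowSums(nn_acc^2))
  nn_acc <- nn_acc / pmax(len, 1e-300)

  list(boundary_faces = bfaces, boundary_normals = nrml,
       boundary_areas = areas, boundary_nodes = bnodes,
       node_normals = nn_acc, node_boundary_areas = na_acc)
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tetrahedra, %d boundary faces\n",
              nrow(x$nodes), nrow(x$tets), nrow(x$boundary_faces)))
  cat(sprintf("  total volume %.4f cm^3 (target edge %.3f cm)\n",
              sum(x$volumes), x$target_edge_cm))
  invisible(x)
}

#' Export a mesh as legacy ASCII VTK
#'
#' Writes an UNSTRUCTURED_GRID file (cell type 10) for visual inspection in
#' ParaView and the like.
#'
#' @param mesh A `tet_mesh`.
#' @param path Output file path.
#' @param point_data Optional named list of per-node numeric vectors.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", "cbxlct mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, digits = 10, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  if (!is.null(point_data) && length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], digits = 10), con)
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK tetrahedral mesh
#'
#' Counterpart of [write_mesh_vtk()]; reads points and tetrahedral cells.
#'
#' @param path VTK file path.
#' @return A list with `nodes` and `tets`.
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- scan(text = lines[(ip + 1):length(lines)], n = 3L * n, quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cells <- scan(text = lines[(ic + 1):length(lines)], n = 5L * m, quiet = TRUE)
  cells <- matrix(cells, ncol = 5, byrow = TRUE)
  stop_if_not(all(cells[, 1] == 4), "only tetrahedral cells supported")
  list(nodes = nodes, tets = cells[, 2:5] + 1L)
}
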