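test_that("cylinder mesh is watertight with outward unit normals", {
  ph <- fx_phantom()
  m <- mesh_cylinder(ph, 0.35)
  # unit normals
  expect_lt(max(abs(sqrt(rowSums(m$boundary_normals^2)) - 1)), 1e-9)
  # closed surface: area-weighted normals sum to zero
  expect_lt(max(abs(colSums(m$boundary_normals * m$boundary_areas))), 1e-10)
  # all faces are shared by exactly 1 (boundary) or 2 (interior) tets,
  # enforced during construction; positive volumes
  expect_true(all(m$volumes > 0))
  # boundary conformity: face centroids lie on the cylinder surface
  fc <- (m$nodes[m$boundary_faces[, 1], ] + m$nodes[m$boundary_faces[, 2], ] +
           m$nodes[m$boundary_faces[, 3], ]) / 3
  r <- sqrt(fc[, 1]^2 + fc[, 2]^2)
  on_side <- abs(r - ph$radius_cm) < 0.35
  on_cap <- abs(abs(fc[, 3]) - ph$height_cm / 2) < 1e-9
  expect_true(all(on_side | on_cap))
})

test_that("refinement at least doubles node count and volume converges", {
  ph <- fx_phantom()
  edges <- c(0.6, 0.3, 0.15)
  meshes <- lapply(edges, function(e) mesh_cylinder(ph, e))
  n_nodes <- vapply(meshes, function(m) nrow(m$nodes), numeric(1))
  expect_true(all(diff(n_nodes) > n_nodes[-3]))  # more than doubling
  v_true <- pi * ph$radius_cm^2 * ph$height_cm
  errs <- vapply(meshes, function(m) abs(sum(m$volumes) - v_true) / v_true,
                 numeric(1))
  # within 2% at edge = R/10 and error at least halving per refinement
  expect_lt(errs[3], 0.02)
  expect_true(all(errs[-1] <= errs[-3] / 2 + 1e-12))
})

test_that("edge validation rejects degenerate requests", {
  ph <- fx_phantom()
  expect_error(mesh_cylinder(ph, 0), "edge")
  expect_error(mesh_cylinder(ph, ph$diameter_cm), "edge")
})

test_that("VTK export round-trips nodes and tetrahedra", {
  m <- mesh_cylinder(fx_phantom(), 0.7)
  path <- tempfile(fileext = ".vtk")
  write_mesh_vtk(m, path, point_data = list(z = m$nodes[, 3]))
  back <- read_mesh_vtk(path)
  expect_equal(back$nodes, unname(m$nodes), tolerance = 1e-9)
  expect_equal(back$tets, unname(m$tets))
  unlink(path)
})
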