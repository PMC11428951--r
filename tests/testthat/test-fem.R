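test_that("assembled diffusion system is symmetric positive definite", {
  ph <- fx_phantom()
  m <- mesh_cylinder(ph, 0.7)  # coarse, small enough for a dense eigensolve
  for (scheme in c("galerkin", "monotone")) {
    sys <- assemble_diffusion_system(m, ph$optics, scheme = scheme)
    expect_equal(max(abs(sys$A - Matrix::t(sys$A))), 0)
    ev <- eigen(as.matrix(sys$A), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("zero source gives zero fluence and the solve is linear", {
  ph <- fx_phantom()
  m <- mesh_cylinder(ph, 0.5)
  sys <- assemble_diffusion_system(m, ph$optics)
  n <- nrow(m$nodes)
  phi0 <- solve_fluence(sys, S = numeric(n))
  expect_true(all(phi0 == 0))
  set.seed(3)
  S <- runif(n)
  phi1 <- solve_fluence(sys, S = S)
  phi3 <- solve_fluence(sys, S = 3 * S)
  expect_equal(as.numeric(phi3), 3 * as.numeric(phi1), tolerance = 1e-10)
  expect_lt(attr(phi1, "residual"), 1e-8)
})

test_that("monotone scheme keeps the fluence non-negative", {
  ph <- fx_phantom()
  m <- mesh_cylinder(ph, 0.4)
  sys <- assemble_diffusion_system(m, ph$optics, scheme = "monotone")
  set.seed(5)
  S <- ifelse(runif(nrow(m$nodes)) < 0.05, 1, 0)  # sparse sources
  phi <- solve_fluence(sys, S = S)
  expect_gte(min(phi), -1e-9 * max(phi))
})

test_that("conjugate-gradient and Cholesky solves agree", {
  ph <- fx_phantom()
  m <- mesh_cylinder(ph, 0.5)
  sys <- assemble_diffusion_system(m, ph$optics)
  set.seed(11)
  S <- runif(nrow(m$nodes))
  p1 <- solve_fluence(sys, S = S, method = "chol")
  p2 <- solve_fluence(sys, S = S, method = "cg", tol = 1e-10)
  expect_lt(rel_l2 <- sqrt(sum((p1 - p2)^2)) / sqrt(sum(p1^2)), 1e-7)
})

test_that("emission source is the pointwise excitation product", {
  # 3-node toy: gamma 2, X = (1, 0.5, 0.25), n = (10, 0, 4) -> (20, 0, 2)
  expect_equal(emission_source(c(1, 0.5, 0.25), c(10, 0, 4), gamma = 2),
               c(20, 0, 2))
  expect_equal(emission_source(runif(5), numeric(5)), numeric(5))
  X <- runif(6); n <- runif(6)
  expect_equal(emission_source(X, 2 * n), 2 * emission_source(X, n))
  expect_error(emission_source(c(1, 1), c(-1, 0)), "negative")
  expect_error(emission_source(c(1, 1), c(1)), "same points")
})

test_that("reciprocity holds for the symmetric system", {
  ph <- fx_phantom()
  m <- mesh_cylinder(ph, 0.6)
  sys <- assemble_diffusion_system(m, ph$optics)
  i <- 10L
  j <- m$boundary_nodes[5]
  ei <- numeric(nrow(m$nodes)); ei[i] <- 1
  ej <- numeric(nrow(m$nodes)); ej[j] <- 1
  phi_i <- solve_fluence(sys, rhs = ei)
  phi_j <- solve_fluence(sys, rhs = ej)
  expect_equal(phi_i[j], phi_j[i], tolerance = 1e-8)
})
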