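# Finite-element light transport: P1 (linear tetrahedral) discretization of
# the diffusion equation
#     -div(D grad Phi) + mu_a Phi = S        in the phantom
#     Phi + 2 kappa D (nu . grad Phi) = 0    on the boundary,
# which weakly yields A = D K + mu_a M + (1/(2 kappa)) Mb with K the
# stiffness matrix, M the interior mass matrix, and Mb the boundary mass
# matrix. A is symmetric positive definite.

#' Assemble the FEM diffusion system
#'
#' Two discretization schemes are offered. `"galerkin"` is the consistent
#' P1 Galerkin discretization -- the accurate choice for fluence solves
#' (it converges to the analytic diffusion kernel) but, like any P1 scheme
#' on a mesh with obtuse elements, it can undershoot slightly below zero in
#' regions of steep exponential decay. `"monotone"` applies the discrete
#' maximum-principle correction (positive stiffness off-diagonals moved to
#' the diagonal, row sums preserved; lumped mass matrices): the system
#' matrix becomes an M-matrix, so the fluence from any non-negative source
#' is non-negative everywhere -- the property required of the linear
#' measurement operator, at the price of some added numerical diffusion.
#' Weight-matrix assembly and projection simulation use the monotone scheme.
#'
#' @param mesh A [mesh_cylinder()] mesh.
#' @param optics An [optical_properties()] object (homogeneous coefficients).
#' @param scheme `"galerkin"` (consistent, accurate) or `"monotone"`
#'   (positivity-preserving).
#' @return An object of class `diffusion_system`: sparse symmetric matrix
#'   `A`, interior mass matrix `M` (the source-coupling matrix), boundary
#'   mass matrix `Mb`, plus an environment caching the Cholesky factor.
#' @export
assemble_diffusion_system <- function(mesh, optics,
                                      scheme = c("galerkin", "monotone")) {
  scheme <- match.arg(scheme)
  stop_if_not(inherits(mesh, "tet_mesh"), "`mesh` must be a tet_mesh")
  stop_if_not(inherits(optics, "optical_properties"),
              "`optics` must be optical_properties")
  n <- nrow(mesh$nodes)
  tets <- mesh$tets
  V <- mesh$volumes

  p1 <- mesh$nodes[tets[, 1], , drop = FALSE]
  e1 <- mesh$nodes[tets[, 2], , drop = FALSE] - p1
  e2 <- mesh$nodes[tets[, 3], , drop = FALSE] - p1
  e3 <- mesh$nodes[tets[, 4], , drop = FALSE] - p1
  det6 <- 6 * V  # = det(J) after orientation fix
  cross_rows <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  g2 <- cross_rows(e2, e3) / det6
  g3 <- cross_rows(e3, e1) / det6
  g4 <- cross_rows(e1, e2) / det6
  g1 <- -(g2 + g3 + g4)
  grads <- list(g1, g2, g3, g4)

  nt <- nrow(tets)
  ii <- integer(0); jj <- integer(0); kk <- numeric(0); mm <- numeric(0)
  idx_i <- vector("list", 16); idx_j <- vector("list", 16)
  kv <- vector("list", 16); mv <- vector("list", 16)
  q <- 0
  for (ai in 1:4) for (aj in 1:4) {
    q <- q + 1
    idx_i[[q]] <- tets[, ai]
    idx_j[[q]] <- tets[, aj]
    kv[[q]] <- V * rowSums(grads[[ai]] * grads[[aj]])
    mv[[q]] <- V * (if (ai == aj) 0.1 else 0.05)
  }
  ii <- unlist(idx_i); jj <- unlist(idx_j)
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = unlist(kv), dims = c(n, n))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = unlist(mv), dims = c(n, n))

  bf <- mesh$boundary_faces
  Ab <- mesh$boundary_areas
  bi <- vector("list", 9); bj <- vector("list", 9); bx <- vector("list", 9)
  q <- 0
  for (ai in 1:3) for (aj in 1:3) {
    q <- q + 1
    bi[[q]] <- bf[, ai]; bj[[q]] <- bf[, aj]
    bx[[q]] <- Ab * (if (ai == aj) 1 / 6 else 1 / 12)
  }
  Mb <- Matrix::sparseMatrix(i = unlist(bi), j = unlist(bj), x = unlist(bx),
                             dims = c(n, n))

  K <- (K + Matrix::t(K)) / 2
  M <- (M + Matrix::t(M)) / 2
  if (scheme == "monotone") {
    K <- monotone_stiffness(K)
    M <- Matrix::Diagonal(x = Matrix::rowSums(M))
    Mb <- Matrix::Diagonal(x = Matrix::rowSums(Mb))
  }
  A <- optics$D * K + optics$mu_a * M + Mb / (2 * optics$kappa)
  A <- Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
  structure(
    list(A = A, M = Matrix::forceSymmetric(M), Mb = Mb, optics = optics,
         mesh = mesh, scheme = scheme,
         cache = new.env(parent = emptyenv())),
    class = "diffusion_system"
  )
}

# Discrete maximum-principle fix: positive off-diagonal stiffness entries
# are moved onto the diagonal (preserving row sums), which makes the matrix
# an M-matrix on any mesh.
monotone_stiffness <- function(K) {
  Kt <- methods::as(methods::as(K, "generalMatrix"), "TsparseMatrix")
  pos <- Kt@i != Kt@j & Kt@x > 0
  add <- numeric(nrow(K))
  if (any(pos)) {
    tab <- rowsum(Kt@x[pos], Kt@i[pos] + 1L)
    add[as.integer(rownames(tab))] <- tab
    Kt@x[pos] <- 0
  }
  Matrix::drop0(methods::as(Kt, "CsparseMatrix")) + Matrix::Diagonal(x = add)
}

system_cholesky <- function(system) {
  if (is.null(system$cache$chol)) {
    system$cache$chol <- tryCatch(
      Matrix::Cholesky(system$A, LDL = FALSE, perm = TRUE),
      error = function(e) stop("assembly error: system is singular (",
                               conditionMessage(e), ")", call. = FALSE)
    )
  }
  system$cache$chol
}

# Jacobi-preconditioned conjugate gradient; used for large single-solve
# systems where the Cholesky fill-in is not worth paying.
cg_solve <- function(A, b, tol = 1e-8, maxit = 20000L) {
  dinv <- 1 / Matrix::diag(A)
  x <- numeric(length(b))
  r <- b
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- as.vector(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / bnorm
    if (res <= tol) return(x)
    z <- dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf("solver non-convergence: relative residual %.3e after %d CG iterations",
               res, maxit), call. = FALSE)
}

#' Solve the diffusion system for the photon fluence
#'
#' Solves `A Phi = M S` (for a nodal source density `S`) or `A Phi = rhs`
#' for an explicit load vector (e.g. a point source), to a relative residual
#' of at most `tol`. Small systems are solved by sparse Cholesky (cached and
#' reused across right-hand sides); large single solves fall back to
#' preconditioned conjugate gradients.
#'
#' @param system A [assemble_diffusion_system()] result.
#' @param S Nodal source density (photons per volume), same length as nodes.
#' @param rhs Explicit load vector, mutually exclusive with `S`.
#' @param method `"auto"`, `"chol"` or `"cg"`.
#' @param tol Relative residual tolerance.
#' @return Object of class `fluence_field`: numeric per-node fluence with the
#'   achieved relative residual as attribute `residual`.
#' @export
solve_fluence <- function(system, S = NULL, rhs = NULL,
                          method = c("auto", "chol", "cg"), tol = 1e-8) {
  method <- match.arg(method)
  stop_if_not(inherits(system, "diffusion_system"),
              "`system` must be a diffusion_system")
  stop_if_not(xor(is.null(S), is.null(rhs)), "supply exactly one of `S`, `rhs`")
  n <- nrow(system$A)
  if (!is.null(S)) {
    stop_if_not(length(S) == n, "nodal source has wrong length")
    rhs <- as.vector(system$M %*% S)
  }
  stop_if_not(length(rhs) == n, "load vector has wrong length")
  if (method == "auto") method <- if (n <= 40000L) "chol" else "cg"
  phi <- if (method == "chol") {
    as.vector(Matrix::solve(system_cholesky(system), rhs))
  } else {
    cg_solve(system$A, rhs, tol = tol)
  }
  res <- rel_l2(as.vector(system$A %*% phi), rhs)
  if (!is.finite(res) || res > max(tol, 1e-7))
    stop(sprintf("solver non-convergence: relative residual %.3e", res),
         call. = FALSE)
  structure(phi, residual = res, class = "fluence_field")
}

#' Emission source from X-ray excitation
#'
#' Pointwise product `S = gamma * X * n` of the light yield, the X-ray
#' intensity and the nanoparticle concentration, evaluated at shared sample
#' locations (typically mesh nodes).
#'
#' @param xray_field X-ray intensities at the sample points.
#' @param concentration Nanoparticle concentration at the same points
#'   (non-negative).
#' @param gamma Light yield, positive scalar.
#' @return Numeric vector of emitted source densities.
#' @export
emission_source <- function(xray_field, concentration, gamma = 1) {
  stop_if_not(length(xray_field) == length(concentration),
              "X-ray field and concentration must be sampled at the same points")
  stop_if_not(all(concentration >= 0), "negative concentration")
  check_positive_scalar(gamma, "gamma")
  gamma * xray_field * concentration
}

#' Analytic infinite-medium diffusion kernel
#'
#' Green's function of the diffusion equation for a unit point source in an
#' unbounded homogeneous medium: `exp(-mu_eff r) / (4 pi D r)` with
#' `mu_eff = sqrt(3 mu_a (mu_a + mu_s'))`. Used as the physics oracle for the
#' FEM solver on a large cylinder where boundary effects are negligible at
#' interior radii.
#'
#' @param r_cm Distances from the source (cm), positive.
#' @param optics An [optical_properties()] object.
#' @return Fluence values at the given radii.
#' @export
diffusion_kernel_infinite <- function(r_cm, optics) {
  stop_if_not(all(r_cm > 0), "radii must be positive")
  mu_eff <- sqrt(3 * optics$mu_a * (optics$mu_a + optics$mu_s_prime))
  exp(-mu_eff * r_cm) / (4 * pi * optics$D * r_cm)
}
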