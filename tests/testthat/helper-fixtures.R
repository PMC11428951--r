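# Shared small fixtures, built lazily once per test run.

.fx <- new.env(parent = emptyenv())

fx_optics <- function() optical_properties(mu_a = 0.02, mu_s_prime = 10)

fx_phantom <- function() cylinder_phantom(3.0, 2.3, fx_optics())

# Coarse geometry used by forward-model tests: small grid, few views.
fx_forward <- function() {
  if (is.null(.fx$forward)) {
    phantom <- fx_phantom()
    mesh <- mesh_cylinder(phantom, 0.4)
    grid <- voxel_grid(20, 20, 3, diameter_mm = 30, z_spacing_mm = 1)
    detector <- detector_model(20, 20, extent_cm = 3.2,
                               angles_deg = seq(0, 270, by = 90))
    source <- xray_source()
    system <- assemble_diffusion_system(mesh, phantom$optics,
                                        scheme = "monotone")
    wm <- build_weight_matrix(mesh, grid, detector, source, system = system)
    .fx$forward <- list(phantom = phantom, mesh = mesh, grid = grid,
                        detector = detector, source = source,
                        system = system, wm = wm)
  }
  .fx$forward
}

derive_seeds_exposed <- function(master, n) cbxlct:::derive_seeds(master, n)

rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

# A seeded, well-conditioned small linear system with a non-negative truth.
fx_toy_problem <- function(m = 20, n = 10, seed = 7, noise = 0.01) {
  set.seed(seed)
  W <- matrix(runif(m * n), m, n)
  x_true <- pmax(rnorm(n), 0)
  y <- W %*% x_true + noise * rnorm(m)
  list(W = W, x_true = x_true, y = y)
}

# Tiny network configuration for gradient and shape tests.
fx_tiny_net <- function(...) {
  net_config(input_shape = c(4, 8, 8), output_shape = c(3, 8, 8),
             enc_channels = c(2, 3, 3, 4, 4),
             enc_pools = list(c(2, 2, 2), c(2, 2, 2), c(1, 1, 1),
                              c(1, 2, 2), c(1, 1, 1)),
             bottleneck = 10,
             dec_channels = c(4, 4, 3, 3, 2),
             dec_strides = list(c(1, 2, 2), c(1, 2, 2), c(1, 2, 2),
                                c(1, 1, 1), c(1, 1, 1)),
             dec_start_channels = 4, ...)
}
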