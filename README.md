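# cbxlct

Simulation and reconstruction for cone-beam X-ray luminescence computed
tomography (CB-XLCT).

CB-XLCT excites X-ray-excitable nanophosphors (e.g. Y2O3:Eu3+) inside a
turbid object with a cone-beam source and images the emitted light leaving
the surface from many view angles. Recovering the 3D nanoparticle
concentration `x` from the boundary measurements `y` is a severely
ill-posed inverse problem. This package provides the whole experimental
loop for the simulation study of that problem, for researchers working on
optical/X-ray hybrid tomography:

* **Physics-based forward model.** Lambert–Beer cone-beam excitation
  `X(r) = X(r0) exp(-∫ μt ds)`, emission `S = Γ X n`, finite-element
  solution of the diffusion equation
  `-∇·(D∇Φ) + μa Φ = S`, `D = 1/[3(μs' + μa)]`, with Robin boundary
  condition `Φ + 2κD(ν·∇Φ) = 0`, and orthographic splatting of the
  boundary exitance `J = Φ/(2κ)` onto the camera. Discretized, the chain
  is the linear measurement model `y = W x + ς`; `W` is assembled by an
  adjoint/reciprocity route and is entrywise non-negative by construction
  (a positivity-preserving FEM variant).
* **Synthetic training-set generator** reproducing the published recipe:
  2–3 random cylindrical targets (∅3–4 mm × 4 mm, centres ±10 mm,
  pairwise edge-to-edge distances 0.3–2.5 mm, 50 mg/mL), 24 views every
  15°, optional white Gaussian noise at a prescribed SNR.
* **Four classical solvers** for
  `x = argmin_{x≥0} ||Wx − y||² + λ||x||₁` and relatives: adaptive FISTA
  (step 0.01), T-FISTA (λ = 0.1, 300 iterations), Poisson MLEM
  (800 iterations), and MAP with a Gaussian Markov random-field prior
  minimized by iterative coordinate descent with alternating
  hyperparameter estimation.
* **A 3D encoder–decoder reconstruction network** (five conv blocks →
  two FC bottleneck layers → five transposed-conv blocks, skip
  connections, optional dual-sampling channel attention), trained with
  the composite objective
  `L = MSE(xr, xt) + MSE(xr', xt') + 2·[SSIM-loss(xr, xt) + SSIM-loss(xr', xt')]`
  (primes = target-region crops), implemented from scratch with C++
  convolution kernels and finite-difference-verified gradients.
* **Quantitative evaluation**: Dice at half-maximum, volume-weighted
  CNR, line profiles, connected-component resolvability, and seeded
  experiment recipes (resolution, noise, ablation, multi-target).

## Worked example

Simulate a two-target scan at 30 dB SNR and reconstruct it with T-FISTA:

```r
library(cbxlct)
set.seed(1)

optics   <- optical_properties(mu_a = 0.02, mu_s_prime = 10)  # cm^-1
phantom  <- cylinder_phantom(3.0, 2.3, optics)                # cm
mesh     <- mesh_cylinder(phantom, 0.3)                       # cm edge
grid     <- voxel_grid(32, 32, 5, diameter_mm = 30)
detector <- detector_model(32, 32, extent_cm = 3.2,
                           angles_deg = seq(0, 330, 30))

wm <- build_weight_matrix(mesh, grid, detector, xray_source())
#> weight_matrix: 12288 measurements x 4060 voxels (adjoint assembly)

targets <- make_eed_targets(eed_mm = 1.5)   # two cylinders, 1.5 mm apart
truth   <- rasterize_targets(targets, grid)$truth
y <- add_gaussian_noise(project_volume(wm, truth), snr_db = 30, seed = 7)
#> projection_set: 12 views of 32 x 32 (max 0.01256)

rec <- t_fista(inverse_problem(wm, y))
#> recon_result [t_fista]: 300 iterations, converged = TRUE
#>   objective 237.028 -> 56.3122

vol <- normalize_volume(rec$volume)
dice(vol, truth > 0)        # 0.649
count_components(vol)       # 1  (the two targets are merged at 1.5 mm)
```

The Dice coefficient of 0.65 says the half-maximum region of the
reconstruction overlaps about two thirds of the true target volume; the
single connected component shows this classical solver cannot separate
the pair at a 1.5 mm edge-to-edge distance on this scan geometry —
exactly the resolution question the deep reconstruction targets.

To train the network at desk scale, generate a dataset and call
`train_model()`:

```r
preset <- xlct_preset("sim-scaled")
manifest <- generate_dataset(preset$spec, n_samples = 350,
                             split_fractions = preset$split_fractions,
                             master_seed = 1, out_dir = "dataset", wm = wm)
samples <- lapply(manifest$paths, load_sample)
model <- train_model(samples[manifest$split == "train"],
                     samples[manifest$split == "val"],
                     preset$net_config, preset$train_config)
volume <- predict_volume(model, y)
```

A thin command-line front end (`inst/cli/xlct.R`) wraps the same
functions as `simulate`, `reconstruct` and `evaluate` subcommands.

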