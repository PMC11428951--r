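---
title: "Models and methods: simulation and reconstruction for cone-beam X-ray luminescence CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulation and reconstruction for cone-beam X-ray luminescence CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cbxlct)
```

## The imaging problem

Cone-beam X-ray luminescence computed tomography (CB-XLCT) excites
X-ray-excitable nanophosphors (such as Y2O3:Eu3+) inside a turbid object
with a cone beam and records the emitted visible/NIR light leaving the
surface with a camera at many view angles. The reconstruction unknown is
the 3D nanoparticle concentration $n(r)$.

The forward physics chained by this package is:

1. **Excitation.** The X-ray intensity follows the Lambert–Beer law,
   $X(r) = X(r_0)\exp\{-\int \mu_t\,ds\}$, evaluated analytically along
   source–point rays through the homogeneous cylinder. The emitted source
   density is $S(r) = \Gamma X(r) n(r)$ with light yield $\Gamma$.
2. **Light transport.** In the high-scattering, low-absorption regime the
   diffusion approximation holds:
   $-\nabla\!\cdot\![D\nabla\Phi] + \mu_a\Phi = S$ with
   $D = 1/[3(\mu_s' + \mu_a)]$ and the Robin boundary condition
   $\Phi + 2\kappa D\,(\nu\!\cdot\!\nabla\Phi) = 0$.
3. **Detection.** The boundary exitance $J = \Phi/(2\kappa)$ at
   camera-facing surface nodes is splatted orthographically onto the
   detector grid (bilinear weights, per-node area weighting). Free-space
   lens optics are deliberately not modelled; only relative intensities
   matter downstream because every reconstruction is max-normalized.

Discretizing concentration on a voxel grid and collecting all views yields
the linear measurement model $y = Wx + \varsigma$, where column $j$ of $W$
is the full chain applied to a unit concentration in voxel $j$.

### Units and geometry

Phantom, mesh and optical quantities are in centimetres; targets and the
reconstruction grid in millimetres, with explicit conversions at module
boundaries. The coordinate frame is right-handed with the origin on the
cylinder axis at mid-height and $z$ along the axis. The 7-slice (full
scale) output band is centred on mid-height; the acquisition description never states the
band, and centring matches the symmetric setup. During a scan the object
rotates; in the object frame the source and camera rotate rigidly, with
the X-ray focal spot placed opposite the camera at a configurable
source-to-axis distance (20 cm default). $\Gamma$ and the phantom
$\mu_t$ are not published; the defaults ($\Gamma = 1$,
$\mu_t = 0.3\,\mathrm{cm}^{-1}$) act as a global scale that cancels under
max-normalization.

## Finite-element light transport

The cylinder is meshed by mapping a regular grid on the square onto the
disk (concentric-square map), extruding prism layers, and splitting each
prism into three tetrahedra with the sorted-global-index rule, which makes
the mesh conforming and watertight by construction. P1 elements give the
standard stiffness/mass/boundary-mass system
$A = D K + \mu_a M + M_b/(2\kappa)$, symmetric positive definite.

Two discretizations are provided, because two desirable properties are in
tension on this mesh family:

* `scheme = "galerkin"` — the consistent Galerkin discretization.
  Accurate (the point-source solution matches the infinite-medium kernel
  $\exp(-\mu_{\mathrm{eff}} r)/(4\pi D r)$ within ~10% over
  $r \in [0.3, 1]$ cm at a 1.5 mm mesh), but like any P1 scheme on meshes
  with obtuse elements it can undershoot zero by a few percent of the
  local maximum where the solution decays exponentially.
* `scheme = "monotone"` — positive off-diagonal stiffness entries are
  moved onto the diagonal (row sums preserved) and the mass matrices are
  lumped. The system becomes an M-matrix, so the fluence from any
  non-negative source is non-negative **everywhere**, and therefore every
  entry of $W$ is non-negative exactly. The price is added, direction-
  dependent numerical diffusion: the kernel is biased (error saturates
  around 25–35% rather than converging) and images of symmetric
  configurations carry a mesh-diagonal imprint of order 20%.

Weight-matrix assembly and projection simulation share one monotone
system, which makes the linear operator exactly consistent with the
per-view simulation (relative $L_2$ discrepancy at machine precision) and
exactly linear in concentration, while `solve_fluence()` defaults to the
accurate Galerkin scheme. Small systems are factorized once (sparse
Cholesky) and re-used across right-hand sides; large single solves fall
back to Jacobi-preconditioned conjugate gradients at a $10^{-8}$ relative
residual.

$W$ is assembled by the adjoint/reciprocity route (one back-solve per
boundary node, exploiting the symmetry of $A$) or, as an independently
ordered reference, by one solve per voxel; both agree to machine
precision and the suite asserts it.

## Synthetic training data

The generator reproduces the published recipe: two or three cylindrical
targets per sample, diameters 3 or 4 mm, height 4 mm, centres uniform in
$[-10, 10]$ mm (phantom) or $[-8, 8]$ mm (mouse variant), all pairwise
edge-to-edge distances in $[0.3, 2.5]$ mm, 50 mg/mL concentration.
Placement is rejection sampling with a 10,000-attempt budget; failures
raise rather than silently relaxing constraints. Full scale generates
8000 samples (6000 train / 2000 validation); the mouse variant 4000
(3000/1000). Whether training projections carry noise is not stated in
the source description; the default is noise-free training with noise
applied only in evaluation sweeps, switchable per `sample_spec()`. Target
z-centres jitter within ±1 mm of mid-height so the output band always
contains them. Projections are resized to the network input with exact
area-weighted (anti-aliased) averaging. Normalization — projections by
their stack maximum, truth by the nominal concentration — happens at load
time so raw physical units stay on disk (one serialized container per
sample plus a JSON manifest carrying seeds and a config hash; regeneration
from the manifest is bit-exact).

What the generator deliberately does **not** emulate: anatomical
heterogeneity (homogeneous optics per the phantom study), free-space
camera optics, energy-resolved X-ray spectra, camera PSF/EM gain.
Passing tests therefore validate the method under the idealized,
self-consistent physics of the simulator — not performance on real
detector data.

## Classical reconstruction baselines

All four solve the regularized problem
$x = \arg\min_{x\ge 0} \lVert Wx - y\rVert_2^2 + \lambda\lVert x\rVert_1$
or its statistical analogues, with the published settings:

* **ADFISTA** — FISTA with L1 prox and non-negativity, gradient step
  0.01, adaptive termination (relative solution change below $10^{-6}$,
  cap 2000 iterations; the source only cites the condition, so the
  standard form is used).
* **T-FISTA** — the same family with $\lambda = 0.1$ and exactly 300
  iterations.
* **ADMLEM** — multiplicative Poisson MLEM,
  $x \leftarrow x\,(W^\top(y/(Wx)))/(W^\top 1)$, 800 iterations; negative
  (noise-induced) measurements are clipped to zero with a message;
  all-zero columns are excluded. The Poisson log-likelihood is recorded
  and non-decreasing.
* **MAP-GMRF-ICD** — MAP with a 6-connected Gaussian Markov random-field
  prior (uniform pair weights $1/6$), minimized by voxel-wise iterative
  coordinate descent in fixed raster order with closed-form 1-D updates
  clipped at zero; after every sweep $\sigma^2 = \lVert r\rVert^2/m$ and
  $p^2 = U(x)/n$ are re-estimated in closed form (the cited estimation
  formulas are not reproduced in the source; these are the standard
  ML-type updates).

**Problem normalization.** The published $\lambda$ and step sizes
presuppose an operator scaling the source never states; on the raw
physics scale they degenerate (the solution is identically zero).
`inverse_problem()` therefore normalizes by default: unit-$L_2$ columns
of $W$ (the standard sensitivity compensation for photon-transport
Jacobians, counteracting the exponentially larger sensitivity of
boundary-adjacent voxels), unit spectral norm, and unit-max measurement.
Under this convention $\lambda = 0.1$ puts T-FISTA in its reported
working regime. Solutions are rescaled to original units; for
$\lambda = 0$ the normalization is exactly transparent (verified against
non-negative least squares).

A step-halving safeguard (with momentum restart) guards FISTA against a
step size that exceeds the stability limit of the actual $\lVert W\rVert$.
Multi-view measurements stack view-major with column-major pixels per
view, the fixed convention shared by $W$ and `stack_measurements()`.

## The reconstruction network

The encoder–decoder maps the stacked multi-view projections (depth axis =
views, single channel) to the z-stack of reconstructed slices:

* five encoder blocks of 3×3×3 convolution → batch normalization →
  LeakyReLU(0.2) → max pooling;
* two fully connected bottleneck layers;
* five decoder blocks of stride-(1,2,2) transposed convolution → batch
  normalization → ReLU, with optional dual-sampling channel attention;
* nearest-resized encoder skip connections concatenated at each decoder
  stage (decoder stage $i$ receives encoder block $6-i$);
* a 1×1×1 non-negative output head.

Because 24 views and 7 slices are not power-of-two compatible the source
architecture cannot fix a unique pooling plan; the full-scale schedule
pools depth in the first three blocks (24→12→6→3) and space five times
(128→4), and the decoder starts from an FC-reshaped 7×4×4 map upsampled
spatially five times. All layers, gradients and the Adam optimizer are
implemented in the package (im2col+GEMM C++ kernels for the
convolutions); every gradient path is finite-difference checked in the
suite.

Two design choices came out of measured training behaviour and are
documented as such:

* **Output head.** A hard ReLU head dies irrecoverably on the ~98%-empty
  target volumes (training collapses into the all-zero local optimum and
  all gradients vanish). The non-negative activation is therefore
  softplus with a negative initial bias (output starts near, but not at,
  zero); a linear head with an inference-time clamp is also available and
  exhibits an exactly stationary collapse, so softplus is the default.
* **Dual-sampling attention.** The channel gates measurably impair
  short-run optimization (in a 10-sample overfit probe the loss
  contraction stalls at ~0.15 of its initial value with attention and
  reaches ~0.06 without). The scaled preset disables the module; it stays
  on at full scale and is exercised by the ablation configurations
  (±skip connections, ±ROI loss — all constructible from config alone).

### Training objective

The loss is the composite objective
$\mathcal{L} = \mathcal{L}_{MSE}(x_r, x_t) + \mathcal{L}_{MSE}(x_r', x_t')
+ 2[\mathcal{L}_{SSIM}(x_r, x_t) + \mathcal{L}_{SSIM}(x_r', x_t')]$,
where primes denote the target-region crops (the bounding box of the ROI
mask, expanded in-plane so the SSIM window fits) and
$\mathcal{L}_{SSIM} = 1 - \mathrm{MSSIM}$. SSIM uses an 11×11 Gaussian
window ($\sigma = 1.5$), $C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$ with
$L = 1$ on normalized data, slid over every z-slice at all valid
positions (no padding) and averaged. The printed MSE formula in the
source omits the square on the residual; it is implemented as the mean of
squared differences. Whether the factor-2 SSIM weight was tuned is not
stated; it is treated as fixed.

Training follows the published procedure: Adam, batch 64, 200 epochs,
initial learning rate $2\times 10^{-5}$, halved after 5 epochs without
validation improvement, best-validation parameters retained.

## Evaluation

Reconstructions are max-normalized. Dice binarizes the reconstruction at
a configurable fraction of its maximum (default 50% — the source never
states its binarization rule; half-maximum is standard practice and makes
Dice invariant to monotone rescaling) and compares with the true target
region. CNR uses volume-proportional variance weights
($w_{ROI} + w_{BCK} = 1$) with the background defined as the in-phantom
region outside the true targets. Line profiles sample the normalized
volume trilinearly. Resolvability is quantified as the number of
6-connected components at half-maximum.

`run_experiment()` provides seeded, bit-reproducible recipes: resolution
sweeps (EED 2.0/1.5/1.0 mm), noise sweeps (SNR 30/25/20/15 dB over the
whole projection stack — the per-stack convention is a choice, recorded
in the configuration), randomized held-out cases, and three-target cases.

## The scaled-down study and its honest outcome

The desk-scale configuration used by the test suite and the acceptance
script is a first-class preset: 48×48×5 grid (0.625 mm in-plane, 1 mm
z), 12 views every 30° on a 32×32 detector resized to the 48×48 network
input (the acquisition itself resizes camera frames to the network
resolution, so resizing is part of the pipeline), 2.5 mm mesh, 300
training / 50 validation samples, encoder channels (4,8,16,16,16),
bottleneck 512, batch 4, learning rate $10^{-3}$, 22 epochs. Batch size,
channel widths and epoch count were set from step-time measurements so
the whole pipeline runs in minutes on one CPU.

Under these conditions the package's own measurements are unambiguous:
the from-scratch network reaches a held-out two-target Dice of roughly
0.10–0.18 (a 40-epoch diagnostic continued to ~0.18 with the
train/validation gap already opening), while T-FISTA scores ~0.3–0.4 on
the same cases. The published ordering — the network clearly ahead of
every iterative baseline — emerges from the full-scale regime (6000
training samples, 200 epochs at batch 64, roughly two orders of magnitude
more sample-passes than a desk-scale budget admits). The corresponding
end-to-end expectation in the test suite is therefore expected to fail at
desk scale; it is kept faithful rather than weakened, and the acceptance
script reports the measured Dice values for both methods so the gap is
visible. The noise-robustness direction (30 dB at least as good as
15 dB) does hold for the trained network.

## Numerical choices and limitations

* Mesh volume converges to the analytic cylinder volume (error well
  below 2% at a tenth-radius edge); refinement at least doubles nodes.
* The FEM solver tolerance is $10^{-8}$ (relative); Cholesky factors are
  cached per system.
* Rejection sampling of targets never relaxes constraints; the
  10,000-attempt budget raises on infeasible ranges.
* FISTA momentum restarts on step halving; ICD uses fixed raster order,
  making every solver bit-deterministic for a fixed problem.
* The SSIM window shrinks only via configuration (window size is a
  parameter); ROI crops are expanded to fit it rather than shrinking the
  window silently.
* Degenerate inputs are defined, not special-cased ad hoc: all-zero
  volumes normalize to themselves with a warning, empty-vs-empty Dice is
  1 (logged), zero pooled variance with equal means gives CNR 0 and with
  unequal means infinity (flagged).
* Known limitations: homogeneous optics only; orthographic camera
  without free-space optics; the monotone operator's anisotropic
  numerical diffusion (documented above); desk-scale training does not
  reproduce full-scale network quality.
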