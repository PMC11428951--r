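# Randomized training-set generation: the full-scale recipe draws two or
# three cylindrical nanophosphor targets per sample (diameter 3 or 4 mm,
# height 4 mm, centres within +/-10 mm, pairwise edge-to-edge distances in
# [0.3, 2.5] mm), simulates the multi-view boundary luminescence, resizes the
# projections to the network input size, and rasterizes the ground-truth
# concentration onto the output grid. 8000 samples (6000 train / 2000
# validation) at full scale; the mouse-geometry variant uses +/-8 mm centres
# and 4000 samples (3000/1000).

#' Specification of one synthetic training sample family
#'
#' Collects everything [generate_sample()] needs: the scan geometry, the
#' target randomization ranges and the noise setting. Defaults reproduce the
#' full-scale phantom recipe.
#'
#' @param phantom A [cylinder_phantom()].
#' @param grid Output [voxel_grid()].
#' @param detector A [detector_model()].
#' @param source An [xray_source()].
#' @param n_targets 2, 3, or `"2or3"` to draw uniformly between them.
#' @param diam_choices_mm,height_mm,center_range_mm,eed_range_mm,z_jitter_mm
#'   Target randomization ranges, see [sample_targets()].
#' @param concentration Target concentration (mg/mL).
#' @param snr_db Measurement SNR in dB; `Inf` (the default) generates
#'   noise-free training projections, noise being a property of the
#'   evaluation sweeps.
#' @param input_shape Length-2 pixel shape the projections are resized to
#'   before entering the network (`NULL` keeps the detector resolution).
#' @param gamma Light yield.
#' @return An object of class `sample_spec`.
#' @export
sample_spec <- function(phantom, grid, detector, source,
                        n_targets = "2or3", diam_choices_mm = c(3, 4),
                        height_mm = 4, center_range_mm = 10,
                        eed_range_mm = c(0.3, 2.5), z_jitter_mm = 1,
                        concentration = 50, snr_db = Inf,
                        input_shape = NULL, gamma = 1) {
  stop_if_not(identical(n_targets, "2or3") || n_targets %in% c(2, 3),
              "`n_targets` must be 2, 3 or \"2or3\"")
  structure(list(phantom = phantom, grid = grid, detector = detector,
                 source = source, n_targets = n_targets,
                 diam_choices_mm = diam_choices_mm, height_mm = height_mm,
                 center_range_mm = center_range_mm,
                 eed_range_mm = eed_range_mm, z_jitter_mm = z_jitter_mm,
                 concentration = concentration, snr_db = snr_db,
                 input_shape = input_shape, gamma = gamma),
            class = "sample_spec")
}

#' Area-weighted image resize
#'
#' Resamples an image by exact interval-overlap averaging: every output pixel
#' is the area-weighted mean of the input pixels its footprint covers. The
#' operation is anti-aliased, preserves the mean of smooth images, maps
#' constants to the same constant, never produces negative values from
#' non-negative input, and is the identity when shapes match.
#'
#' @param image Numeric matrix.
#' @param out_shape Length-2 integer target shape.
#' @return Resized matrix.
#' @export
resize_projection <- function(image, out_shape) {
  stop_if_not(is.matrix(image), "`image` must be a matrix")
  stop_if_not(length(out_shape) == 2 && all(out_shape >= 1),
              "`out_shape` must be two positive sizes")
  R1 <- overlap_matrix(nrow(image), out_shape[1])
  R2 <- overlap_matrix(ncol(image), out_shape[2])
  R1 %*% image %*% t(R2)
}

# Row-stochastic (n_out x n_in) interval-overlap operator on [0, 1].
overlap_matrix <- function(n_in, n_out) {
  lo_o <- (seq_len(n_out) - 1) / n_out; hi_o <- seq_len(n_out) / n_out
  lo_i <- (seq_len(n_in) - 1) / n_in; hi_i <- seq_len(n_in) / n_in
  M <- matrix(0, n_out, n_in)
  for (o in seq_len(n_out)) {
    ov <- pmin(hi_o[o], hi_i) - pmax(lo_o[o], lo_i)
    pos <- ov > 0
    M[o, pos] <- ov[pos]
  }
  M / rowSums(M)
}

#' Generate one synthetic training sample
#'
#' Draws targets, simulates projections (through the weight matrix when one
#' is supplied -- the two routes agree by the operator-consistency property
#' -- or the full per-view FEM chain otherwise), optionally adds noise,
#' resizes the projections, and rasterizes the ground truth. Bit-reproducible
#' for a fixed seed.
#'
#' @param spec A [sample_spec()].
#' @param seed Integer seed for this sample.
#' @param wm Optional precomputed [build_weight_matrix()] for the spec's
#'   geometry (recommended when generating many samples).
#' @return An object of class `training_sample`: `projections` (array
#'   `n_views x h x w`), `truth` (nx x ny x nz mg/mL), `roi_mask`,
#'   `targets`, `seed`.
#' @export
generate_sample <- function(spec, seed, wm = NULL) {
  stop_if_not(inherits(spec, "sample_spec"), "`spec` must be a sample_spec")
  set.seed(as.integer(seed))
  n_t <- if (identical(spec$n_targets, "2or3")) sample(2:3, 1) else spec$n_targets
  tgs <- sample_targets(spec$phantom, n_targets = n_t,
                        diam_choices_mm = spec$diam_choices_mm,
                        height_mm = spec$height_mm,
                        center_range_mm = spec$center_range_mm,
                        eed_range_mm = spec$eed_range_mm,
                        concentration = spec$concentration,
                        z_jitter_mm = spec$z_jitter_mm, seed = NULL)
  ras <- rasterize_targets(tgs, spec$grid)
  proj <- if (!is.null(wm)) {
    project_volume(wm, ras$truth)
  } else {
    simulate_projections(spec$phantom, tgs, spec$detector, spec$source,
                         grid = spec$grid, gamma = spec$gamma)
  }
  if (is.finite(spec$snr_db)) proj <- add_gaussian_noise(proj, spec$snr_db)
  imgs <- proj$images
  if (!is.null(spec$input_shape) &&
      !all(dim(imgs)[2:3] == spec$input_shape)) {
    out <- array(0, c(dim(imgs)[1], spec$input_shape))
    for (v in seq_len(dim(imgs)[1])) {
      out[v, , ] <- resize_projection(imgs[v, , ], spec$input_shape)
    }
    imgs <- out
  }
  structure(list(projections = imgs, truth = ras$truth,
                 roi_mask = ras$roi_mask, targets = tgs,
                 angles_deg = proj$angles_deg, seed = as.integer(seed)),
            class = "training_sample")
}

#' Generate a dataset of synthetic samples on disk
#'
#' Writes one serialized container per sample plus a JSON manifest holding
#' file paths, disjoint train/validation split labels, per-sample seeds
#' derived from the master seed, and a hash of the generation config, so the
#' whole dataset can be regenerated bit-exactly from the manifest.
#'
#' @param spec A [sample_spec()].
#' @param n_samples Number of samples (full-scale recipe: 8000 phantom /
#'   4000 mouse).
#' @param split_fractions Named fractions summing to 1, e.g.
#'   `c(train = 0.75, val = 0.25)`.
#' @param master_seed Integer master seed.
#' @param out_dir Output directory (created if needed).
#' @param wm Optional precomputed weight matrix (strongly recommended).
#' @return The manifest, an object of class `dataset_manifest`, also written
#'   to `<out_dir>/manifest.json`.
#' @export
generate_dataset <- function(spec, n_samples, split_fractions = c(train = 0.75, val = 0.25),
                             master_seed = 1, out_dir, wm = NULL) {
  stop_if_not(is_scalar_num(n_samples) && n_samples >= 1,
              "`n_samples` must be >= 1")
  stop_if_not(abs(sum(split_fractions) - 1) < 1e-9,
              "`split_fractions` must sum to 1")
  stop_if_not(!is.null(names(split_fractions)),
              "`split_fractions` must be named")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_samples <- as.integer(n_samples)
  seeds <- derive_seeds(master_seed, n_samples)
  counts <- floor(split_fractions * n_samples)
  rem <- n_samples - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  split <- rep(names(counts), counts)

  paths <- character(n_samples)
  for (i in seq_len(n_samples)) {
    s <- generate_sample(spec, seeds[i], wm = wm)
    paths[i] <- file.path(out_dir, sprintf("sample_%05d.rds", i))
    saveRDS(s, paths[i])
  }
  manifest <- structure(
    list(paths = paths, split = split, seeds = seeds,
         master_seed = as.integer(master_seed),
         n_samples = n_samples,
         config_hash = config_hash(spec),
         concentration = spec$concentration),
    class = "dataset_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Load a generated sample, optionally normalized for training
#'
#' Normalization happens at load time so raw physical units stay on disk:
#' projections are divided by their stack maximum and the truth volume by the
#' nominal concentration, matching the max-intensity normalization applied to
#' reconstructions.
#'
#' @param path Path to a sample written by [generate_dataset()], or a
#'   `training_sample` object.
#' @param normalize Apply load-time normalization.
#' @param concentration Concentration used to scale the truth to `[0, 1]`.
#' @return A `training_sample`.
#' @export
load_sample <- function(path, normalize = TRUE, concentration = 50) {
  s <- if (inherits(path, "training_sample")) path else readRDS(path)
  if (normalize) {
    m <- max(s$projections)
    if (m > 0) s$projections <- s$projections / m
    if (concentration > 0) s$truth <- s$truth / concentration
  }
  s
}
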