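# Experiment presets and reproducible evaluation recipes: resolution sweeps
# over edge-to-edge distance, noise-robustness sweeps over SNR, multi-target
# cases, and ablation configurations, each yielding per-case and aggregate
# Dice/CNR reports.

#' Study presets
#'
#' Bundles a coherent set of geometry, acquisition, meshing, network and
#' training configurations.
#'
#' * `"sim-full"`: the full-scale simulation study -- 3.0 x 2.3 cm phantom
#'   (mu_a 0.02, mu_s' 10 cm^-1), 128 x 128 x 7 grid at 1 mm z-resolution,
#'   24 views every 15 degrees, 8000 samples (6000/2000 split), batch 64,
#'   200 epochs, learning rate 2e-5.
#' * `"sim-scaled"`: the CPU-scale configuration used by the test suite --
#'   48 x 48 x 5 grid, 12 views every 30 degrees on a 32 x 32 detector
#'   resized to 48 x 48 network input, coarser mesh, a narrower network,
#'   batch 4, 20 epochs, learning rate 1e-3.
#' * `"mouse-full"`: the mouse-geometry variant of the training recipe
#'   (centres within +/-8 mm, 4000 samples, 3000/1000 split); the cylinder
#'   geometry stands in for the animal surface.
#'
#' @param name Preset name.
#' @return A list with components `phantom`, `grid`, `detector`, `source`,
#'   `mesh_edge_cm`, `spec` (a [sample_spec()]), `net_config`,
#'   `train_config`, `n_samples`, `split_fractions`.
#' @export
xlct_preset <- function(name = c("sim-scaled", "sim-full", "mouse-full")) {
  name <- match.arg(name)
  optics <- optical_properties(mu_a = 0.02, mu_s_prime = 10)
  phantom <- cylinder_phantom(3.0, 2.3, optics)
  if (name == "sim-scaled") {
    grid <- voxel_grid(48, 48, 5, diameter_mm = 30, z_spacing_mm = 1)
    detector <- detector_model(32, 32, extent_cm = 3.2,
                               angles_deg = seq(0, 330, by = 30))
    spec <- sample_spec(phantom, grid, detector, xray_source(),
                        n_targets = 2, center_range_mm = 10,
                        input_shape = c(48, 48))
    return(list(name = name, phantom = phantom, grid = grid,
                detector = detector, source = xray_source(),
                mesh_edge_cm = 0.25, spec = spec,
                net_config = net_config_scaled(),
                train_config = train_config(batch_size = 4, epochs = 22,
                                            lr = 1e-3),
                n_samples = 350,
                split_fractions = c(train = 300 / 350, val = 50 / 350)))
  }
  grid <- voxel_grid(128, 128, 7, diameter_mm = 30, z_spacing_mm = 1)
  detector <- detector_model(128, 128, extent_cm = 3.2,
                             angles_deg = seq(0, 345, by = 15))
  center_range <- if (name == "mouse-full") 8 else 10
  n <- if (name == "mouse-full") 4000 else 8000
  spec <- sample_spec(phantom, grid, detector, xray_source(),
                      n_targets = "2or3", center_range_mm = center_range,
                      input_shape = c(128, 128))
  list(name = name, phantom = phantom, grid = grid, detector = detector,
       source = xray_source(), mesh_edge_cm = 0.15, spec = spec,
       net_config = net_config_full(),
       train_config = train_config(batch_size = 64, epochs = 200, lr = 2e-5),
       n_samples = n, split_fractions = c(train = 0.75, val = 0.25))
}

#' Symmetric two-target resolution case
#'
#' Two equal cylinders on the x axis separated by a prescribed edge-to-edge
#' distance, the standard spatial-resolution configuration of such studies.
#'
#' @param eed_mm Edge-to-edge distance (the sweeps use 2.0, 1.5, 1.0 mm).
#' @param diameter_mm,height_mm,concentration Target properties.
#' @param z_mm Common z centre.
#' @return List of two [xlct_target()]s.
#' @export
make_eed_targets <- function(eed_mm, diameter_mm = 4, height_mm = 4,
                             concentration = 50, z_mm = 0) {
  r <- diameter_mm / 2
  x <- eed_mm / 2 + r
  list(xlct_target(c(-x, 0, z_mm), diameter_mm, height_mm, concentration),
       xlct_target(c(x, 0, z_mm), diameter_mm, height_mm, concentration))
}

#' The four ablation configurations
#'
#' Skip connections and the ROI loss toggled independently, constructible
#' from configuration alone.
#'
#' @param base A [net_config()] (the scaled configuration by default).
#' @return Named list of four lists, each with `net_config` and
#'   `use_roi_loss`.
#' @export
ablation_configs <- function(base = net_config_scaled()) {
  variant <- function(skip) {
    net_config(input_shape = base$input_shape, output_shape = base$output_shape,
               enc_channels = base$enc_channels, enc_pools = base$enc_pools,
               bottleneck = base$bottleneck, dec_channels = base$dec_channels,
               dec_strides = base$dec_strides,
               dec_start_channels = base$dec_start_channels,
               skip = skip, dual_sampling = base$dual_sampling,
               leaky_slope = base$leaky_slope,
               out_bias_init = base$out_bias_init,
               output_activation = base$output_activation)
  }
  list(
    none = list(net_config = variant(FALSE), use_roi_loss = FALSE),
    no_skip = list(net_config = variant(FALSE), use_roi_loss = TRUE),
    no_roi = list(net_config = variant(TRUE), use_roi_loss = FALSE),
    full = list(net_config = variant(TRUE), use_roi_loss = TRUE)
  )
}

# Dice + CNR of one reconstruction against the rasterized truth; background
# is the in-phantom region outside the true target region.
evaluate_case <- function(volume, truth, phantom_mask, dice_threshold = 0.5) {
  roi <- truth > 0
  bck <- phantom_mask & !roi
  v <- normalize_volume(volume)
  data.frame(dice = dice(v, roi, dice_threshold),
             cnr = cnr(v, roi, bck),
             n_components = count_components(v, dice_threshold))
}

#' Run an evaluation experiment recipe
#'
#' Simulates seeded test cases, reconstructs them with every requested
#' method, and reports per-case and aggregate Dice/CNR metrics. Fixed seeds
#' make the whole experiment bit-reproducible.
#'
#' Recipe types: `"resolution"` enumerates symmetric two-target cases at
#' `eed_mm` (default 2.0 / 1.5 / 1.0 mm); `"noise"` crosses `eed_mm` with
#' `snr_db` (default 30 / 25 / 20 / 15 dB); `"random"` draws `n_cases`
#' randomized target sets (2 or 3 targets per `n_targets`); `"multi_target"`
#' is `"random"` with three targets.
#'
#' @param recipe List with `type`, optionally `eed_mm`, `snr_db`, `n_cases`,
#'   `n_targets`, `seed`, `dice_threshold`.
#' @param methods Character subset of
#'   `c("deep", "adfista", "tfista", "admlem", "map")`; must be non-empty.
#' @param wm A [build_weight_matrix()] for the preset geometry.
#' @param model A [train_model()] result (required when `"deep"` is used).
#' @param spec The [sample_spec()] describing the geometry (defaults to the
#'   scaled preset's).
#' @param out_dir Optional directory for CSV and JSON reports.
#' @return Object of class `metric_report`: data frame of per-case metrics
#'   with an `aggregate` attribute (mean Dice/CNR by method and condition).
#' @export
run_experiment <- function(recipe, methods, wm, model = NULL,
                           spec = NULL, out_dir = NULL) {
  all_methods <- c("deep", "adfista", "tfista", "admlem", "map")
  stop_if_not(length(methods) >= 1 && all(methods %in% all_methods),
              "`methods` must be a non-empty subset of the known methods")
  stop_if_not(!("deep" %in% methods) || inherits(model, "trained_model"),
              "`model` is required for the deep method")
  if (is.null(spec)) spec <- xlct_preset("sim-scaled")$spec
  seed <- recipe$seed %||% 1L
  thr <- recipe$dice_threshold %||% 0.5
  type <- recipe$type %||% "resolution"

  cases <- build_cases(recipe, type, spec, seed)
  stop_if_not(length(cases) >= 1, "recipe produced no cases")
  pmask <- phantom_voxel_mask(spec$phantom, spec$grid)

  # simulate measurements once per case
  for (i in seq_along(cases)) {
    ras <- rasterize_targets(cases[[i]]$targets, spec$grid)
    proj <- project_volume(wm, ras$truth)
    if (is.finite(cases[[i]]$snr_db)) {
      proj <- add_gaussian_noise(proj, cases[[i]]$snr_db,
                                 seed = seed + 7919L * i)
    }
    cases[[i]]$truth <- ras$truth
    cases[[i]]$proj <- proj
  }

  rows <- list()
  add_row <- function(case, method, ev) {
    rows[[length(rows) + 1]] <<- cbind(
      data.frame(case = case$id, method = method, eed_mm = case$eed_mm,
                 snr_db = case$snr_db, n_targets = length(case$targets)),
      ev)
  }
  for (method in methods) {
    if (method == "deep") {
      for (cs in cases) {
        vol <- predict_volume(model, cs$proj)
        add_row(cs, method, evaluate_case(vol, cs$truth, pmask, thr))
      }
    } else if (method %in% c("tfista", "adfista")) {
      Y <- vapply(cases, function(cs) stack_measurements(cs$proj),
                  numeric(nrow(wm$W)))
      prob <- inverse_problem(wm, Y)
      res <- if (method == "tfista") t_fista(prob) else adfista(prob)
      for (i in seq_along(cases)) {
        vol <- coeffs_to_volume(wm, res$x[, i])
        add_row(cases[[i]], method, evaluate_case(vol, cases[[i]]$truth,
                                                  pmask, thr))
      }
    } else {
      for (cs in cases) {
        prob <- inverse_problem(wm, cs$proj)
        res <- if (method == "admlem") admlem(prob) else map_gmrf_icd(prob)
        add_row(cs, method, evaluate_case(res$volume, cs$truth, pmask, thr))
      }
    }
  }
  report <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(dice, cnr) ~ method + eed_mm + snr_db,
                          data = report, FUN = mean)
  attr(report, "aggregate") <- agg
  class(report) <- c("metric_report", "data.frame")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(report),
                     file.path(out_dir, "metrics_per_case.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(per_case = as.data.frame(report),
                              aggregate = agg),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

build_cases <- function(recipe, type, spec, seed) {
  cases <- list()
  if (type == "resolution") {
    eeds <- recipe$eed_mm %||% c(2.0, 1.5, 1.0)
    snr <- recipe$snr_db %||% 30
    for (e in eeds) {
      cases[[length(cases) + 1]] <- list(
        id = sprintf("eed%.1f", e), targets = make_eed_targets(e),
        eed_mm = e, snr_db = snr)
    }
  } else if (type == "noise") {
    eeds <- recipe$eed_mm %||% c(2.0, 1.5, 1.0)
    snrs <- recipe$snr_db %||% c(30, 25, 20, 15)
    for (e in eeds) for (s in snrs) {
      cases[[length(cases) + 1]] <- list(
        id = sprintf("eed%.1f_snr%g", e, s), targets = make_eed_targets(e),
        eed_mm = e, snr_db = s)
    }
  } else if (type %in% c("random", "multi_target")) {
    n_cases <- recipe$n_cases %||% 20
    n_targets <- if (type == "multi_target") 3 else (recipe$n_targets %||% 2)
    seeds <- derive_seeds(seed, n_cases)
    snr <- recipe$snr_db %||% Inf
    for (i in seq_len(n_cases)) {
      tg <- sample_targets(spec$phantom, n_targets = n_targets,
                           diam_choices_mm = spec$diam_choices_mm,
                           height_mm = spec$height_mm,
                           center_range_mm = spec$center_range_mm,
                           eed_range_mm = spec$eed_range_mm,
                           concentration = spec$concentration,
                           z_jitter_mm = spec$z_jitter_mm, seed = seeds[i])
      ee <- if (length(tg) == 2) compute_eed(tg[[1]], tg[[2]]) else NA_real_
      cases[[length(cases) + 1]] <- list(
        id = sprintf("case%03d", i), targets = tg, eed_mm = ee, snr_db = snr)
    }
  } else {
    stop("unknown recipe type: ", type, call. = FALSE)
  }
  cases
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report: %d rows\n", nrow(x)))
  print(attr(x, "aggregate"))
  invisible(x)
}
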