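# Volume I/O: NIfTI with voxel spacing metadata (reconstructions) and YAML /
# JSON round-tripping of phantom + target configurations with explicit units
# in the key names.

#' Write / read a reconstruction volume as NIfTI
#'
#' Voxel spacing (mm) is stored in the header's pixdim.
#'
#' @param volume nx x ny x nz numeric array.
#' @param grid The [voxel_grid()] the volume lives on.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path` (write) or a list with `volume` and `spacing_mm` (read).
#' @export
write_volume_nifti <- function(volume, grid, path) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- c(grid$dx_mm, grid$dy_mm, grid$dz_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(volume = array(as.vector(img), dim(img)),
       spacing_mm = as.numeric(RNifti::pixdim(img)))
}

#' Write / read phantom and target configurations
#'
#' Plain YAML (or JSON by extension) with units spelled out in the key names
#' (`diameter_cm`, `center_mm`, ...).
#'
#' @param phantom A [cylinder_phantom()].
#' @param targets Optional list of [xlct_target()]s.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path` (write); a list with `phantom` and `targets` (read).
#' @export
write_scan_config <- function(phantom, targets = list(), path) {
  cfg <- list(
    phantom = list(diameter_cm = phantom$diameter_cm,
                   height_cm = phantom$height_cm,
                   mu_a_cm1 = phantom$optics$mu_a,
                   mu_s_prime_cm1 = phantom$optics$mu_s_prime,
                   kappa = phantom$optics$kappa,
                   xray_mu_t_cm1 = phantom$xray_mu_t),
    targets = lapply(targets, function(tg) {
      list(center_mm = tg$center_mm, diameter_mm = tg$diameter_mm,
           height_mm = tg$height_mm,
           concentration_mg_ml = tg$concentration,
           light_yield = tg$light_yield)
    })
  )
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' @rdname write_scan_config
#' @export
read_scan_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  ph <- cfg$phantom
  phantom <- cylinder_phantom(ph$diameter_cm, ph$height_cm,
                              optical_properties(ph$mu_a_cm1,
                                                 ph$mu_s_prime_cm1,
                                                 ph$kappa %||% 1),
                              xray_mu_t = ph$xray_mu_t_cm1 %||% 0.3)
  targets <- lapply(cfg$targets, function(tg) {
    xlct_target(unlist(tg$center_mm), tg$diameter_mm, tg$height_mm,
                tg$concentration_mg_ml, tg$light_yield %||% 1)
  })
  list(phantom = phantom, targets = targets)
}
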