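# ggplot2 figures for reconstructions, line profiles, and training history.

#' Plot one z-slice of a volume
#'
#' @param volume nx x ny x nz array.
#' @param slice Slice index (middle slice by default).
#' @param title Optional title.
#' @return A ggplot object.
#' @export
plot_slice <- function(volume, slice = NULL, title = NULL) {
  stop_if_not(length(dim(volume)) == 3, "`volume` must be 3D")
  if (is.null(slice)) slice <- ceiling(dim(volume)[3] / 2)
  sl <- volume[, , slice]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a line profile
#'
#' @param profile A [intensity_profile()] result (or several in a named
#'   list, overlaid).
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  if (inherits(profile, "profile_line")) profile <- list(profile = profile)
  df <- do.call(rbind, lapply(names(profile), function(nm) {
    cbind(as.data.frame(profile[[nm]]), series = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$intensity,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position along line", y = "normalized intensity") +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' Train/validation total loss per epoch of a [train_model()] result.
#'
#' @param model A `trained_model`.
#' @return A ggplot object.
#' @export
plot_training_history <- function(model) {
  h <- model$history
  df <- rbind(data.frame(epoch = h$epoch, loss = h$train_total, set = "train"),
              data.frame(epoch = h$epoch, loss = h$val_total, set = "validation"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "composite loss") +
    ggplot2::theme_minimal()
}
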