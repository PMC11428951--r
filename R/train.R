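# Network training: Adam with the composite MSE + SSIM + ROI objective,
# plateau learning-rate decay, best-validation checkpointing.

#' Training configuration
#'
#' Defaults follow the full-scale training recipe: Adam, batch size 64,
#' 200 epochs, initial learning rate 2e-5, halved after 5 epochs without
#' validation improvement.
#'
#' @param batch_size Samples per optimization step.
#' @param epochs Training epochs.
#' @param lr Initial learning rate.
#' @param lr_factor Multiplicative decay on plateau (exactly 0.5 by default).
#' @param patience Epochs without validation improvement before decay.
#' @param warmup_steps Optimizer steps over which the learning rate ramps
#'   linearly from zero to `lr` (0 disables warmup).
#' @param seed Seed controlling initialization and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 64, epochs = 200, lr = 2e-5,
                         lr_factor = 0.5, patience = 5, warmup_steps = 0,
                         seed = 1) {
  stop_if_not(batch_size >= 1 && epochs >= 1 && lr > 0 && lr_factor > 0 &&
                patience >= 1 && warmup_steps >= 0,
              "invalid training configuration")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 lr_factor = lr_factor, patience = as.integer(patience),
                 warmup_steps = as.integer(warmup_steps),
                 seed = as.integer(seed)),
            class = "train_config")
}

# (nx, ny, nz) volume <-> (D=z, H=x, W=y) network tensor
vol_to_tensor <- function(v) aperm(v, c(3, 1, 2))
tensor_to_vol <- function(t3) aperm(t3, c(2, 3, 1))

# Assemble a batch: inputs (D,H,W,1,B) from the projection stacks, plus the
# per-sample truth volumes and ROI masks for the loss.
make_batch <- function(samples, idx) {
  d <- dim(samples[[idx[1]]]$projections)
  B <- length(idx)
  x <- array(0, c(d, 1, B))
  for (b in seq_len(B)) x[, , , 1, b] <- samples[[idx[b]]]$projections
  x
}

batch_loss_and_grad <- function(y, samples, idx, params, want_grad = TRUE) {
  B <- length(idx)
  comp <- c(mse_full = 0, mse_roi = 0, ssim_loss_full = 0, ssim_loss_roi = 0,
            total = 0)
  gy <- if (want_grad) array(0, dim(y)) else NULL
  for (b in seq_len(B)) {
    s <- samples[[idx[b]]]
    vol <- tensor_to_vol(y[, , , 1, b])
    lc <- composite_loss(vol, s$truth, s$roi_mask, params,
                         want_grad = want_grad)
    comp <- comp + c(lc$mse_full, lc$mse_roi, lc$ssim_loss_full,
                     lc$ssim_loss_roi, lc$total) / B
    if (want_grad) gy[, , , 1, b] <- vol_to_tensor(lc$grad) / B
  }
  list(components = comp, grad = gy)
}

#' Train the reconstruction network
#'
#' Runs mini-batch Adam on the composite objective over normalized training
#' samples, evaluates the validation loss each epoch, halves the learning
#' rate after `patience` epochs without validation improvement, and keeps
#' the parameters of the best validation epoch.
#'
#' @param train_samples,val_samples Lists of normalized `training_sample`
#'   objects (see [load_sample()]).
#' @param config A [net_config()].
#' @param tcfg A [train_config()].
#' @param ssim An [ssim_params()] for the loss.
#' @param verbose Print per-epoch progress.
#' @return An object of class `trained_model`: the network (best-validation
#'   parameters restored), the configs, and a per-epoch `history` data frame
#'   with decomposed loss components.
#' @export
train_model <- function(train_samples, val_samples, config,
                        tcfg = train_config(), ssim = ssim_params(),
                        verbose = FALSE) {
  stop_if_not(length(train_samples) >= 1 && length(val_samples) >= 1,
              "need non-empty train and validation sets")
  net <- build_network(config, seed = tcfg$seed)
  state <- adam_init(net$param_index)
  set.seed(tcfg$seed + 1L)
  lr <- tcfg$lr
  best_val <- Inf
  best_snap <- snapshot_params(net)
  stall <- 0L
  tstep <- 0L
  hist <- list()
  n <- length(train_samples)
  for (epoch in seq_len(tcfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / tcfg$batch_size))
    tr_comp <- 0
    for (bt in batches) {
      x <- make_batch(train_samples, bt)
      fw <- network_forward(net, x, training = TRUE)
      lg <- batch_loss_and_grad(fw$y, train_samples, bt, ssim)
      stop_if_not(is.finite(lg$components["total"]),
                  "training aborted: non-finite loss")
      for (e in net$envs) zero_grads(e)
      network_backward(net, fw$cache, lg$grad)
      tstep <- tstep + 1L
      lr_eff <- if (tcfg$warmup_steps > 0 && tstep <= tcfg$warmup_steps) {
        lr * tstep / tcfg$warmup_steps
      } else lr
      state <- adam_step(net$param_index, state, lr_eff, tstep)
      tr_comp <- tr_comp + lg$components / length(batches)
    }
    val_comp <- evaluate_loss(net, val_samples, ssim,
                              batch_size = tcfg$batch_size)
    if (val_comp["total"] < best_val - 1e-9) {
      best_val <- val_comp["total"]
      best_snap <- snapshot_params(net)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= tcfg$patience) {
        lr <- lr * tcfg$lr_factor
        stall <- 0L
      }
    }
    hist[[epoch]] <- data.frame(
      epoch = epoch, lr = lr,
      train_total = tr_comp["total"], train_mse_full = tr_comp["mse_full"],
      train_mse_roi = tr_comp["mse_roi"],
      train_ssim_full = tr_comp["ssim_loss_full"],
      train_ssim_roi = tr_comp["ssim_loss_roi"],
      val_total = val_comp["total"], row.names = NULL)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2g",
                      epoch, tr_comp["total"], val_comp["total"], lr))
    }
  }
  restore_params(net, best_snap)
  structure(list(network = net, config = config, train_config = tcfg,
                 ssim_params = ssim, best_val = best_val,
                 history = do.call(rbind, hist)),
            class = "trained_model")
}

# Mean loss components over a sample list (evaluation mode, no gradients).
evaluate_loss <- function(net, samples, ssim, batch_size = 16) {
  n <- length(samples)
  comp <- 0
  batches <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  for (bt in batches) {
    x <- make_batch(samples, bt)
    fw <- network_forward(net, x, training = FALSE, keep_cache = FALSE)
    lg <- batch_loss_and_grad(fw$y, samples, bt, ssim, want_grad = FALSE)
    comp <- comp + lg$components * length(bt) / n
  }
  comp
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model: %d epochs, best validation loss %.5f\n",
              nrow(x$history), x$best_val))
  print(x$network)
  invisible(x)
}

#' Reconstruct a volume with a trained network
#'
#' Normalizes the projection stack by its maximum, resizes it to the network
#' input shape if needed, and runs a deterministic evaluation-mode forward
#' pass. The output is non-negative by construction and lives on the
#' reconstruction grid in `[0, 1]` units of the training concentration.
#'
#' @param model A [train_model()] result.
#' @param projections A [projection_set()] or a `(views, h, w)` array.
#' @return Reconstructed volume, an `nx x ny x nz` array.
#' @export
predict_volume <- function(model, projections) {
  stop_if_not(inherits(model, "trained_model"), "`model` must be a trained_model")
  imgs <- if (inherits(projections, "projection_set")) projections$images
          else projections
  stop_if_not(length(dim(imgs)) == 3, "projections must be (views, h, w)")
  ishape <- model$config$input_shape
  stop_if_not(dim(imgs)[1] == ishape[1],
              "view count does not match the model input")
  if (!all(dim(imgs)[2:3] == ishape[2:3])) {
    out <- array(0, c(ishape[1], ishape[2], ishape[3]))
    for (v in seq_len(dim(imgs)[1])) {
      out[v, , ] <- resize_projection(imgs[v, , ], ishape[2:3])
    }
    imgs <- out
  }
  m <- max(imgs)
  if (m > 0) imgs <- imgs / m
  x <- array(imgs, c(dim(imgs), 1, 1))
  fw <- network_forward(model$network, x, training = FALSE, keep_cache = FALSE)
  tensor_to_vol(fw$y[, , , 1, 1])
}

#' Save / load a trained model
#'
#' Stores the parameter snapshot with the architecture and training
#' configuration in a single serialized file.
#'
#' @param model A `trained_model`.
#' @param path Destination path.
#' @return `path` (save) or the restored `trained_model` (load).
#' @export
save_model <- function(model, path) {
  obj <- list(config = model$config, train_config = model$train_config,
              ssim_params = model$ssim_params, best_val = model$best_val,
              history = model$history,
              params = snapshot_params(model$network))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  net <- build_network(obj$config, seed = 1)
  restore_params(net, obj$params)
  structure(list(network = net, config = obj$config,
                 train_config = obj$train_config,
                 ssim_params = obj$ssim_params, best_val = obj$best_val,
                 history = obj$history),
            class = "trained_model")
}
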