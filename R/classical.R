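# Classical iterative solvers for the regularized inverse problem
#     x = argmin_{x >= 0} ||W x - y||_2^2 + lambda ||x||_beta
# (beta = 1 here), plus a Poisson MLEM solver and a MAP estimator with a
# Gaussian Markov random-field prior minimized by iterative coordinate
# descent with alternating hyperparameter estimation.

#' Linear inverse problem container
#'
#' Pairs a weight matrix with a stacked measurement vector. When built from a
#' [build_weight_matrix()] object the reconstruction can be reshaped back
#' onto the voxel grid and the GMRF prior knows the 3D neighbourhood.
#'
#' The raw physics operator and measurements carry arbitrary intensity
#' units, and boundary-adjacent voxels have exponentially larger
#' sensitivity than deep ones. By default the problem is therefore
#' normalized before solving: the columns of `W` are scaled to unit L2 norm
#' (the standard sensitivity compensation for photon-transport Jacobians),
#' the whole operator to unit spectral norm, and each measurement column to
#' unit maximum. Solver step sizes and regularization weights apply on this
#' normalized scale (where the baseline settings operate); solutions are
#' rescaled back to the original units, which is exactly transparent for
#' `lambda = 0`.
#'
#' @param W A `weight_matrix` or a plain numeric matrix.
#' @param y A [projection_set()], or a numeric vector (stacked view-major),
#'   or a matrix whose columns are independent measurement vectors (solved
#'   simultaneously).
#' @param normalize Apply the sensitivity/spectral/measurement
#'   normalization described above.
#' @return An object of class `inverse_problem`.
#' @export
inverse_problem <- function(W, y, normalize = TRUE) {
  wm <- NULL
  if (inherits(W, "weight_matrix")) { wm <- W; W <- wm$W }
  stop_if_not(is.matrix(W), "`W` must be a matrix or weight_matrix")
  if (inherits(y, "projection_set")) y <- stack_measurements(y)
  y <- if (is.matrix(y)) y else matrix(as.numeric(y), ncol = 1)
  stop_if_not(nrow(W) == nrow(y),
              "row count of W must equal the measurement length")
  xscale_vox <- rep(1, ncol(W))
  y_scale <- rep(1, ncol(y))
  if (normalize) {
    cn <- sqrt(colSums(W^2))
    cn[cn == 0] <- 1
    W <- sweep(W, 2, cn, "/")
    w_scale <- operator_norm(W)
    stop_if_not(w_scale > 0, "W is identically zero")
    W <- W / w_scale
    y_scale <- apply(abs(y), 2, max)
    y_scale[y_scale == 0] <- 1
    y <- sweep(y, 2, y_scale, "/")
    xscale_vox <- 1 / (cn * w_scale)
  }
  structure(list(W = W, y = y, wm = wm,
                 xscale_vox = xscale_vox, yscale = y_scale,
                 cache = new.env(parent = emptyenv())),
            class = "inverse_problem")
}

# Map solutions of the normalized problem back to original units.
rescale_solution <- function(problem, x) {
  sweep(x * problem$xscale_vox, 2, problem$yscale, "*")
}

# Gram matrix of the (normalized) operator, computed once per problem.
problem_gram <- function(problem) {
  if (is.null(problem$cache$G)) problem$cache$G <- crossprod(problem$W)
  problem$cache$G
}

# Largest singular value by power iteration on W'W (deterministic start).
operator_norm <- function(W, iters = 30) {
  v <- rep(1, ncol(W)) + seq_len(ncol(W)) / ncol(W)
  v <- v / sqrt(sum(v^2))
  s <- 0
  for (i in seq_len(iters)) {
    u <- crossprod(W, W %*% v)
    s <- sqrt(sqrt(sum(u^2)))
    if (s == 0) return(0)
    v <- u / sqrt(sum(u^2))
  }
  s
}

#' Soft-thresholding operator
#'
#' `sign(v) * max(|v| - t, 0)`, the proximal operator of the L1 penalty.
#'
#' @param v Numeric input.
#' @param t Threshold, non-negative.
#' @return Shrunk values.
#' @examples
#' soft_threshold(0.5, 0.2)   # 0.3
#' soft_threshold(-0.1, 0.2)  # 0
#' @export
soft_threshold <- function(v, t) {
  stop_if_not(all(t >= 0), "threshold must be non-negative")
  sign(v) * pmax(abs(v) - t, 0)
}

new_recon_result <- function(x, problem, trace, iterations, converged,
                             method, settings) {
  vol <- NULL
  if (!is.null(problem$wm) && is.null(dim(x)))
    vol <- coeffs_to_volume(problem$wm, x)
  structure(list(x = x, volume = vol, objective_trace = trace,
                 iterations = iterations, converged = converged,
                 method = method, settings = settings),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("recon_result [%s]: %d iterations, converged = %s\n",
              x$method, x$iterations, x$converged))
  tr <- x$objective_trace
  if (length(tr)) cat(sprintf("  objective %.6g -> %.6g\n",
                              tr[1], tr[length(tr)]))
  invisible(x)
}

# Shared FISTA engine (accelerated proximal gradient with non-negative L1
# prox). Columns of y are solved simultaneously with a shared step size.
# A safeguard halves the step and restarts the momentum if the objective
# increases, since stability at a fixed step depends on ||W||.
fista_engine <- function(problem, lambda, step, max_iter, tol, adaptive) {
  stop_if_not(lambda >= 0, "lambda must be >= 0")
  check_positive_scalar(step, "step")
  W <- problem$W; y <- problem$y
  n <- ncol(W); k <- ncol(y)
  G <- problem_gram(problem)  # gradient via the cached Gram matrix
  Wty <- crossprod(W, y)
  yty <- colSums(y^2)
  obj <- function(x) {
    colSums(x * (G %*% x)) - 2 * colSums(x * Wty) + yty + lambda * colSums(x)
  }
  x <- matrix(0, n, k)
  z <- x
  tmom <- 1
  o_prev <- obj(x)
  trace <- matrix(NA_real_, max_iter, k)
  halvings <- 0
  it <- 0
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1
    grad <- 2 * (G %*% z - Wty)
    x_new <- pmax(z - step * grad - step * lambda, 0)
    o_new <- obj(x_new)
    if (any(o_new > o_prev + 1e-10 * (abs(o_prev) + 1)) && halvings < 30) {
      step <- step / 2
      halvings <- halvings + 1
      message(sprintf("fista: objective increase, halving step to %g", step))
      z <- x
      tmom <- 1
      it <- it - 1
      next
    }
    stop_if_not(all(is.finite(o_new)), "divergence: non-finite objective")
    t_new <- (1 + sqrt(1 + 4 * tmom^2)) / 2
    z <- x_new + ((tmom - 1) / t_new) * (x_new - x)
    delta <- sqrt(colSums((x_new - x)^2)) /
      pmax(sqrt(colSums(x^2)), 1e-12)
    x <- x_new
    tmom <- t_new
    trace[it, ] <- o_new
    o_prev <- o_new
    if (adaptive && all(delta < tol)) { converged <- TRUE; break }
  }
  list(x = x, trace = trace[seq_len(it), , drop = FALSE], iterations = it,
       converged = converged || !adaptive, step = step)
}

#' Adaptive FISTA (L1) reconstruction
#'
#' FISTA iterations with L1 proximal step and non-negativity projection,
#' gradient step size 0.01, stopping when the relative solution change drops
#' below `tol` (the adaptive termination) or `max_iter` is reached.
#'
#' @param problem An [inverse_problem()].
#' @param lambda L1 regularization weight.
#' @param step Gradient step size (0.01 per the baseline setting).
#' @param tol Relative-change stopping tolerance.
#' @param max_iter Iteration cap.
#' @return A `recon_result` with non-negative solution and objective trace.
#' @export
adfista <- function(problem, lambda = 0.1, step = 0.01, tol = 1e-6,
                    max_iter = 2000) {
  stop_if_not(inherits(problem, "inverse_problem"), "need an inverse_problem")
  r <- fista_engine(problem, lambda, step, max_iter, tol, adaptive = TRUE)
  xs <- rescale_solution(problem, r$x)
  x <- if (ncol(problem$y) == 1) as.vector(xs) else xs
  new_recon_result(x, problem, as.vector(r$trace), r$iterations, r$converged,
                   "adfista", list(lambda = lambda, step = step, tol = tol,
                                   max_iter = max_iter, final_step = r$step))
}

#' Fixed-budget FISTA (T-FISTA) reconstruction
#'
#' The same algorithm family as [adfista()] but with an empirically fixed
#' regularization weight (0.1) and a fixed iteration budget (300), no
#' adaptive stop.
#'
#' @inheritParams adfista
#' @param iterations Fixed number of iterations (default 300).
#' @return A `recon_result`.
#' @export
t_fista <- function(problem, lambda = 0.1, iterations = 300, step = 0.01) {
  stop_if_not(inherits(problem, "inverse_problem"), "need an inverse_problem")
  r <- fista_engine(problem, lambda, step, iterations, tol = 0,
                    adaptive = FALSE)
  xs <- rescale_solution(problem, r$x)
  x <- if (ncol(problem$y) == 1) as.vector(xs) else xs
  new_recon_result(x, problem, as.vector(r$trace), r$iterations, TRUE,
                   "t_fista", list(lambda = lambda, step = step,
                                   iterations = iterations,
                                   final_step = r$step))
}

#' Poisson MLEM reconstruction
#'
#' Multiplicative maximum-likelihood EM updates for Poisson-distributed
#' projections: `x <- x * (W' (y / (W x))) / (W' 1)`, run for a fixed number
#' of iterations (800 in the baseline setting). Negative measurements (which
#' Gaussian noise can produce) are clipped to zero with a message; columns of
#' W with zero sum are unidentifiable and excluded. The Poisson
#' log-likelihood is recorded each iteration and is non-decreasing.
#'
#' @param problem An [inverse_problem()] (single measurement vector).
#' @param iterations Number of MLEM iterations.
#' @param x_init Positive initial value (uniform 1 by default).
#' @return A `recon_result`; `objective_trace` holds the log-likelihood.
#' @export
admlem <- function(problem, iterations = 800, x_init = 1) {
  stop_if_not(inherits(problem, "inverse_problem"), "need an inverse_problem")
  stop_if_not(ncol(problem$y) == 1, "admlem solves one measurement at a time")
  W <- problem$W
  y <- as.vector(problem$y)
  if (any(y < 0)) {
    message(sprintf("admlem: clipping %d negative measurements to 0",
                    sum(y < 0)))
    y <- pmax(y, 0)
  }
  s <- colSums(W)
  active <- s > 0
  if (!all(active)) message(sprintf(
    "admlem: excluding %d all-zero weight columns", sum(!active)))
  Wa <- W[, active, drop = FALSE]
  sa <- s[active]
  x <- rep(as.numeric(x_init), sum(active))
  stop_if_not(all(x > 0), "x_init must be positive")
  eps <- 1e-300
  ll <- numeric(iterations)
  for (it in seq_len(iterations)) {
    yhat <- as.vector(Wa %*% x)
    ratio <- ifelse(yhat > 0, y / pmax(yhat, eps), 0)  # 0/0 guarded as 0
    x <- x * as.vector(crossprod(Wa, ratio)) / sa
    ll[it] <- sum(y[y > 0] * log(pmax(yhat[y > 0], eps))) - sum(yhat)
  }
  xf <- numeric(ncol(W))
  xf[active] <- x
  xf <- as.vector(rescale_solution(problem, matrix(xf, ncol = 1)))
  new_recon_result(xf, problem, ll, iterations, TRUE, "admlem",
                   list(iterations = iterations, x_init = x_init))
}

# 6-connected neighbour lists over the retained voxels of a weight matrix,
# or a 1D chain for plain-matrix toy problems.
gmrf_neighbors <- function(problem) {
  wm <- problem$wm
  n <- ncol(problem$W)
  if (is.null(wm)) {
    return(lapply(seq_len(n), function(i) {
      c(if (i > 1) i - 1L, if (i < n) i + 1L)
    }))
  }
  g <- wm$grid
  lut <- integer(g$nx * g$ny * g$nz)
  lut[wm$voxel_idx] <- seq_along(wm$voxel_idx)
  i0 <- wm$voxel_idx - 1L
  ix <- i0 %% g$nx; iy <- (i0 %/% g$nx) %% g$ny; iz <- i0 %/% (g$nx * g$ny)
  offs <- list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
               c(0, 0, -1), c(0, 0, 1))
  nb_mat <- matrix(0L, length(i0), 6)
  for (k in seq_along(offs)) {
    jx <- ix + offs[[k]][1]; jy <- iy + offs[[k]][2]; jz <- iz + offs[[k]][3]
    ok <- jx >= 0 & jx < g$nx & jy >= 0 & jy < g$ny & jz >= 0 & jz < g$nz
    lin <- jx + jy * g$nx + jz * g$nx * g$ny + 1L
    v <- integer(length(i0))
    v[ok] <- lut[lin[ok]]
    nb_mat[, k] <- v
  }
  apply(nb_mat, 1, function(r) r[r > 0], simplify = FALSE)
}

# Pairwise GMRF prior energy U(x) = sum_{i~j} b (x_i - x_j)^2 (each pair
# counted once); invariant under constant shifts of x.
gmrf_prior_energy <- function(x, neighbors, b_weight = 1 / 6) {
  u <- 0
  for (i in seq_along(x)) {
    nb <- neighbors[[i]]
    if (length(nb)) u <- u + sum(b_weight * (x[i] - x[nb])^2)
  }
  u / 2
}

#' MAP reconstruction with a GMRF prior via iterative coordinate descent
#'
#' Minimizes `||Wx - y||^2 / (2 sigma^2) + U(x) / (2 p^2)` over `x >= 0`,
#' where `U` is a 6-connected Gaussian Markov random-field energy with
#' uniform pair weights. Each sweep performs closed-form one-dimensional
#' updates per voxel in fixed raster order (clipped at zero); after each
#' sweep the hyperparameters are re-estimated in closed form from the
#' current residual and prior energy (`sigma^2 = ||r||^2/m`, `p^2 = U/n`),
#' unless fixed values are supplied.
#'
#' @param problem An [inverse_problem()] (single measurement vector).
#' @param sweeps Maximum number of full ICD sweeps.
#' @param tol Relative objective-change stopping tolerance.
#' @param sigma2,p2 Fixed hyperparameters (NULL = estimate alternately).
#' @param b_weight Uniform pair weight of the GMRF (1/6 for 6-neighbourhoods).
#' @return A `recon_result`; `objective_trace` holds the MAP objective
#'   evaluated at the hyperparameters in force during each sweep, and
#'   `settings$hyper` the per-sweep hyperparameter history.
#' @export
map_gmrf_icd <- function(problem, sweeps = 30, tol = 1e-6,
                         sigma2 = NULL, p2 = NULL, b_weight = 1 / 6) {
  stop_if_not(inherits(problem, "inverse_problem"), "need an inverse_problem")
  stop_if_not(ncol(problem$y) == 1, "map_gmrf_icd solves one measurement at a time")
  W <- problem$W
  y <- as.vector(problem$y)
  n <- ncol(W); m <- nrow(W)
  nbrs <- gmrf_neighbors(problem)
  cn2 <- colSums(W^2)
  estimate <- is.null(sigma2) || is.null(p2)
  s2 <- if (is.null(sigma2)) max(mean(y^2), 1e-12) else sigma2
  pp2 <- if (is.null(p2)) max(mean(y^2), 1e-12) else p2

  x <- numeric(n)
  r <- -y                      # residual W x - y at x = 0
  objective <- function(s2_, p2_) {
    sum(r^2) / (2 * s2_) + gmrf_prior_energy(x, nbrs, b_weight) / (2 * p2_)
  }
  trace <- numeric(0)
  hyper <- list()
  o_prev <- objective(s2, pp2)
  converged <- FALSE
  for (sw in seq_len(sweeps)) {
    for (j in seq_len(n)) {
      nb <- nbrs[[j]]
      deg <- length(nb)
      a <- 2 * cn2[j] / (2 * s2) + b_weight * deg / pp2
      if (a <= 0) next
      wj <- W[, j]
      bb <- (cn2[j] * x[j] - sum(wj * r)) / s2 +
        (if (deg) b_weight * sum(x[nb]) else 0) / pp2
      x_new <- max(0, bb / a)
      dx <- x_new - x[j]
      if (dx != 0) {
        r <- r + wj * dx
        x[j] <- x_new
      }
    }
    o_sweep <- objective(s2, pp2)   # objective at the sweep's hyperparameters
    trace <- c(trace, o_sweep)
    hyper[[sw]] <- c(sigma2 = s2, p2 = pp2)
    if (estimate) {
      u <- gmrf_prior_energy(x, nbrs, b_weight)
      if (is.null(sigma2)) s2 <- max(sum(r^2) / m, 1e-12)
      if (is.null(p2) && u > 0) pp2 <- max(u / n, 1e-12)
      stop_if_not(is.finite(s2) && is.finite(pp2),
                  "non-finite hyperparameter estimate")
    }
    if (abs(o_sweep - o_prev) <= tol * (abs(o_prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    o_prev <- objective(s2, pp2)
  }
  x <- as.vector(rescale_solution(problem, matrix(x, ncol = 1)))
  new_recon_result(x, problem, trace, length(trace),
                   converged, "map_gmrf_icd",
                   list(sweeps = sweeps, tol = tol, b_weight = b_weight,
                        hyper = do.call(rbind, hyper)))
}
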