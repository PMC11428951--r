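# Internal helpers: argument checking, unit conversion, hashing, seed derivation.

stop_if_not <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_positive_scalar <- function(x, name) {
  stop_if_not(is_scalar_num(x) && x > 0,
              sprintf("`%s` must be a single positive finite number", name))
  invisible(x)
}

mm_to_cm <- function(x) x / 10
cm_to_mm <- function(x) x * 10

#' @keywords internal
rotmat_z <- function(angle_deg) {
  th <- angle_deg * pi / 180
  matrix(c(cos(th), sin(th), 0,
           -sin(th), cos(th), 0,
           0, 0, 1), nrow = 3)
}

# Small FNV-1a hash of a serialized R object; used to fingerprint generation
# configs in dataset manifests (no cryptographic strength needed).
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Derive a stream of per-task seeds from one master seed, each < 2^31.
derive_seeds <- function(master_seed, n) {
  stopifnot(is_scalar_num(master_seed), n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master_seed %% 2^31))
  sample.int(.Machine$integer.max, n)
}

rel_l2 <- function(a, b) {
  d <- sqrt(sum((a - b)^2))
  s <- sqrt(sum(b^2))
  if (s == 0) return(if (d == 0) 0 else Inf)
  d / s
}
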