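# Shared helpers: unit conversions, RNG scoping, geometry.

# b-value conversions. User-facing b is s/mm^2; everything internal is SI
# (s/m^2, m^2/s, T/m, rad/s/T).  1 s/mm^2 == 1e6 s/m^2.
b_smm2_to_si <- function(b) b * 1e6
b_si_to_smm2 <- function(b) b / 1e6

#' Hydrogen gyromagnetic ratio (rad s^-1 T^-1)
#' @keywords internal
GAMMA_H <- 2.6752219e8

# Physical constants (SI)
PLANCK_H <- 6.62607015e-34
BOLTZMANN_KB <- 1.380649e-23

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  Keeps generation deterministic without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of sub-seeds (< 2^31) from a master seed; used to give each
# simulated volume its own independent noise stream.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

vnorm <- function(v) sqrt(sum(v^2))

unit_vector <- function(v, tol = 1e-6, what = "vector") {
  n <- vnorm(v)
  if (abs(n - 1) > tol)
    stop(sprintf("%s must be unit-norm (|v| = %.8g)", what, n), call. = FALSE)
  v / n
}

# Deterministic quasi-uniform antipodal direction set (spherical Fibonacci
# lattice on the upper hemisphere).  Used for powder averages.
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n              # upper hemisphere only: antipodal models
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# world mm -> continuous voxel index (0-based) for an affine whose voxel
# centers sit at integer indices.
world_to_voxel <- function(points, affine) {
  stopifnot(is.matrix(points), ncol(points) == 3)
  inv <- solve(affine)
  h <- cbind(points, 1) %*% t(inv)
  h[, 1:3, drop = FALSE]
}

voxel_to_world <- function(idx, affine) {
  h <- cbind(idx, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

log_msg <- function(..., verbose = getOption("dwiphantom.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(...))
  invisible(NULL)
}
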