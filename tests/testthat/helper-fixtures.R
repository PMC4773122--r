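# Shared fixtures: small substrates and schemes, built in code.

small_recipe <- function(seed = 7L, grid = 32L, ...) {
  substrate_recipe(grid_shape = rep(grid, 3L), rng_seed = seed, ...)
}

# cached small substrate (the 32^3 rasterization takes a couple of seconds)
small_substrate <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(generate_numerical_brain(small_recipe()))
    cache
  }
})

# single straight x-axis bundle, no cavity/blobs: every segment is (1,0,0)
straight_recipe <- function(seed = 3L) {
  substrate_recipe(grid_shape = c(32L, 32L, 32L), rng_seed = seed,
                   bundles = list(list(type = "straight", axis = c(1, 0, 0),
                                       radius_mm = 2.5,
                                       n_streamlines = 40)),
                   csf_cavity = NULL, dgm_blobs = list())
}

# tiny scheme for signal-level tests: 1 b0 + n directions at one shell
tiny_scheme <- function(n_dirs = 12L, bval = 1000, n_b0 = 1L, seed = 1L) {
  gradient_scheme(n_dirs = n_dirs, bvals = bval, n_b0 = n_b0, seed = seed)
}

reference_pulse <- function(bval = 1000) {
  pulse_params(12.9e-3, 21.8e-3, b_smm2 = bval)
}

# trims a protocol's scheme to the first b0 plus `n` DW rows (speed)
trim_protocol <- function(proto, n = 6L) {
  dw <- which(proto$scheme$b_smm2 > 0)
  keep <- c(which(proto$scheme$b_smm2 == 0)[1], dw[seq_len(n)])
  sch <- proto$scheme[keep, ]
  rownames(sch) <- NULL
  class(sch) <- c("gradient_scheme", "data.frame")
  attr(sch, "seed") <- attr(proto$scheme, "seed")
  proto$scheme <- sch
  proto
}
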