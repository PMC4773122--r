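# Tractogram -> per-voxel segment-direction field, and the voxel-wise WM
# attenuation: the arithmetic mean of the single-fiber WM model over all
# streamline segments assigned to the voxel.

#' Assign streamline segments to voxels
#'
#' Each consecutive point pair of a streamline is one segment; a segment
#' belongs to the voxel containing its midpoint (the step size never exceeds
#' the voxel size in the supported protocols, so midpoint assignment and
#' face-splitting agree to within one segment).  Segments whose midpoint
#' falls outside the grid are dropped and tallied.
#'
#' @param tractogram a [tractogram] in the same world frame as `grid`.
#' @param grid a [tissue_fraction_map] supplying the grid geometry.
#' @return object of class `segment_direction_field`: `counts` (3D array
#'   N(r)), `directions` (list of unit-direction matrices keyed by voxel
#'   linear index as `character`), `dropped` (segment tally), plus grid
#'   geometry.
#' @export
assign_segments <- function(tractogram, grid) {
  stopifnot(inherits(tractogram, "tractogram"),
            inherits(grid, "tissue_fraction_map"))
  gs <- grid$grid_shape
  sl <- tractogram$streamlines
  if (length(sl)) {
    a <- do.call(rbind, lapply(sl, function(s) s[-nrow(s), , drop = FALSE]))
    b <- do.call(rbind, lapply(sl, function(s) s[-1, , drop = FALSE]))
    mid <- (a + b) / 2
    dirs <- b - a
    dirs <- dirs / sqrt(rowSums(dirs^2))
    idx <- floor(world_to_voxel(mid, grid$affine) + 0.5)  # half-up tie-break
    inside <- idx[, 1] >= 0 & idx[, 1] < gs[1] &
              idx[, 2] >= 0 & idx[, 2] < gs[2] &
              idx[, 3] >= 0 & idx[, 3] < gs[3]
    dropped <- sum(!inside)
    idx <- idx[inside, , drop = FALSE]
    dirs <- dirs[inside, , drop = FALSE]
    lin <- idx[, 1] + gs[1] * (idx[, 2] + gs[2] * idx[, 3]) + 1
  } else {
    dirs <- matrix(0, 0, 3); lin <- integer(0); dropped <- 0L
  }
  counts <- array(0L, dim = gs)
  if (length(lin)) {
    tab <- table(lin)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  directions <- if (length(lin))
    lapply(split.data.frame(dirs, lin), function(m)
      `dimnames<-`(as.matrix(m), NULL)) else list()
  if (dropped > 0)
    log_msg("assign_segments: %d segment(s) outside the grid dropped", dropped)
  structure(list(counts = counts, directions = directions,
                 dropped = dropped, grid_shape = gs, affine = grid$affine),
            class = "segment_direction_field")
}

#' @export
print.segment_direction_field <- function(x, ...) {
  cat("<segment_direction_field>", sum(x$counts), "segments in",
      sum(x$counts > 0), "voxels;", x$dropped, "dropped\n")
  invisible(x)
}

#' Export the per-voxel segment count map for QC
#'
#' @param field a [segment_direction_field].
#' @param path `.nii` output path.
#' @export
write_count_map <- function(field, path) {
  write_nifti(array(as.double(field$counts), dim = field$grid_shape),
              path, affine = field$affine)
}

# Vectorized attenuation of a compartment spec over many cos^2(angle) values
# between gradient and fiber.  ct2 is the squared dot product; everything
# else comes from the pulse.
attenuation_spec_ct2 <- function(spec, pulse, ct2) {
  b <- pulse$b_s_per_m2
  switch(spec$kind,
    isotropic = rep(exp(-b * spec$MD), length(ct2)),
    zeppelin = exp(-b * (spec$d_perp + (spec$d_par - spec$d_perp) * ct2)),
    cylinder = {
      S <- gpd_sum(spec$d, spec$R, pulse$delta_s, pulse$Delta_s)
      exp(-b * ct2 * spec$d -
            2 * pulse$gamma^2 * pulse$G_T_per_m^2 * (1 - ct2) * S)
    },
    mixture = {
      out <- 0
      for (i in seq_along(spec$specs))
        out <- out + spec$weights[i] *
          attenuation_spec_ct2(spec$specs[[i]], pulse, ct2)
      out
    },
    stop("unknown compartment kind: ", spec$kind))
}

#' Voxel-wise WM attenuation from the segment-direction field
#'
#' The WM attenuation of a voxel is the arithmetic mean over its N(r)
#' streamline segments of the single-fiber WM model evaluated at each
#' segment direction.  For fiber-free voxels the powder average is used when
#' `powder_fallback = TRUE`.
#'
#' @param field a [segment_direction_field].
#' @param r voxel index, 0-based integer triple.
#' @param models a [tissue_models] set.
#' @param pulse a [pulse_params].
#' @param grad_dir unit gradient direction.
#' @param powder_fallback allow N(r) = 0.
#' @return scalar attenuation.
#' @export
wm_attenuation_voxel <- function(field, r, models = tissue_models(), pulse,
                                 grad_dir, powder_fallback = FALSE) {
  stopifnot(inherits(field, "segment_direction_field"))
  gs <- field$grid_shape
  lin <- r[1] + gs[1] * (r[2] + gs[2] * r[3]) + 1
  dirs <- field$directions[[as.character(lin)]]
  if (is.null(dirs)) {
    if (!powder_fallback)
      stop(sprintf("no streamline segments in voxel (%d,%d,%d)",
                   r[1], r[2], r[3]))
    log_msg("powder fallback at voxel (%d,%d,%d)", r[1], r[2], r[3])
    return(powder_average(models$WM, pulse, grad_dir))
  }
  grad_dir <- unit_vector(grad_dir, what = "grad_dir")
  ct2 <- as.vector(dirs %*% grad_dir)^2
  mean(attenuation_spec_ct2(models$WM, pulse, ct2))
}

# All-voxel WM attenuation map for one gradient direction (scanner hot
# path).  Returns the full 3D array with `fallback_value` where N(r) = 0.
wm_attenuation_map <- function(field, models, pulse, grad_dir,
                               fallback_value = NA_real_) {
  out <- array(fallback_value, dim = field$grid_shape)
  if (!length(field$directions)) return(out)
  lin <- as.integer(names(field$directions))
  dirs <- do.call(rbind, field$directions)
  n <- vapply(field$directions, nrow, 0L)
  ct2 <- as.vector(dirs %*% grad_dir)^2
  A <- attenuation_spec_ct2(models$WM, pulse, ct2)
  grp <- rep(seq_along(n), n)
  out[lin] <- as.vector(tapply(A, grp, mean))
  out
}
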