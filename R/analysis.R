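# Validation-side estimators: log-linear diffusion tensor fitting (MD/FA),
# mixture-weight recovery by least squares, and streamline-count
# connectivity matrices.

#' Log-linear diffusion tensor fit
#'
#' Ordinary least squares on log-signals with the standard 7-column design
#' (intercept and the six unique b-matrix elements), followed by
#' eigen-decomposition.  Voxels with non-positive signals are flagged and
#' excluded (returned as NA).
#'
#' @param signals numeric matrix, voxels x volumes (a single voxel may be a
#'   plain vector).
#' @param scheme a [gradient_scheme] matching the columns.
#' @return list of class `tensor_fit`: `tensors` (list of 3x3 matrices),
#'   `MD` (m^2/s), `FA`, `evals` (voxels x 3, descending), `excluded`
#'   (logical).
#' @export
fit_dti <- function(signals, scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  if (ncol(signals) != nrow(scheme))
    stop("signals have ", ncol(signals), " volumes but the scheme has ",
         nrow(scheme))
  if (sum(scheme$b_smm2 > 0) < 6 || !any(scheme$b_smm2 == 0))
    stop("tensor fit needs >= 6 DW directions and >= 1 b = 0 volume")
  # fit in s/mm^2 units (the SI design is numerically singular against the
  # unit intercept column); convert the tensor back to m^2/s afterwards
  b <- scheme$b_smm2
  g <- as.matrix(scheme[, c("gx", "gy", "gz")])
  X <- cbind(1,
             -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2],
             -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  nvox <- nrow(signals)
  excluded <- apply(signals <= 0, 1, any)
  if (any(excluded))
    log_msg("fit_dti: %d voxel(s) with non-positive signals excluded",
            sum(excluded))
  XtXi <- solve(crossprod(X))
  tensors <- vector("list", nvox)
  MD <- rep(NA_real_, nvox); FA <- rep(NA_real_, nvox)
  evals <- matrix(NA_real_, nvox, 3)
  for (i in which(!excluded)) {
    beta <- XtXi %*% crossprod(X, log(signals[i, ]))
    Dt <- 1e-6 * matrix(c(beta[2], beta[5], beta[6],   # mm^2/s -> m^2/s
                          beta[5], beta[3], beta[7],
                          beta[6], beta[7], beta[4]), 3, 3)
    ev <- sort(eigen(Dt, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    md <- mean(ev)
    fa <- if (all(ev == 0)) 0 else
      sqrt(1.5 * sum((ev - md)^2) / sum(ev^2))
    tensors[[i]] <- Dt; MD[i] <- md; FA[i] <- fa; evals[i, ] <- ev
  }
  structure(list(tensors = tensors, MD = MD, FA = FA, evals = evals,
                 excluded = excluded), class = "tensor_fit")
}

#' Recover a two-component mixture weight by least squares
#'
#' Solves `observed = w * A + (1 - w) * B` for the scalar weight w over all
#' samples, clipped to [0, 1].  Exact when `observed` was generated by the
#' mixture.
#'
#' @param observed,basis_a,basis_b numeric vectors of equal length (>= 2).
#' @return weight in [0, 1].
#' @export
recover_fraction <- function(observed, basis_a, basis_b) {
  stopifnot(length(observed) == length(basis_a),
            length(observed) == length(basis_b))
  if (length(observed) < 2) stop("need >= 2 observations")
  d <- basis_a - basis_b
  if (sum(d^2) < .Machine$double.eps * sum(basis_a^2))
    stop("basis signals are identical: weight not identifiable")
  w <- sum((observed - basis_b) * d) / sum(d^2)
  min(1, max(0, w))
}

#' Streamline-count connectivity matrix
#'
#' For each streamline the parcel labels at its two endpoints are looked up
#' in `labels`; if both are valid (> 0) and distinct the pair's count is
#' incremented once.  Streamlines with an endpoint outside the grid are
#' skipped and tallied.
#'
#' @param tract a [tractogram].
#' @param labels integer 3D array of parcel ids (0 = background).
#' @param affine voxel-to-world transform of the label grid.
#' @param n_parcels number of parcels (default `max(labels)`).
#' @return list of class `connectivity_matrix`: `counts` (symmetric, zero
#'   diagonal), `skipped_outside`, `skipped_invalid`.
#' @export
connectivity_matrix <- function(tract, labels, affine = diag(4),
                                n_parcels = max(labels)) {
  stopifnot(inherits(tract, "tractogram"), length(dim(labels)) == 3)
  gs <- dim(labels)
  counts <- matrix(0L, n_parcels, n_parcels)
  skipped_outside <- 0L; skipped_invalid <- 0L
  ends <- lapply(tract$streamlines, function(s) s[c(1, nrow(s)), ])
  for (e in ends) {
    idx <- floor(world_to_voxel(e, affine) + 0.5)
    if (any(idx < 0) || any(idx[, 1] >= gs[1]) || any(idx[, 2] >= gs[2]) ||
        any(idx[, 3] >= gs[3])) {
      skipped_outside <- skipped_outside + 1L
      next
    }
    la <- labels[idx[1, 1] + 1, idx[1, 2] + 1, idx[1, 3] + 1]
    lb <- labels[idx[2, 1] + 1, idx[2, 2] + 1, idx[2, 3] + 1]
    if (la < 1 || lb < 1 || la == lb) {
      skipped_invalid <- skipped_invalid + 1L
      next
    }
    counts[la, lb] <- counts[la, lb] + 1L
    counts[lb, la] <- counts[lb, la] + 1L
  }
  structure(list(counts = counts, skipped_outside = skipped_outside,
                 skipped_invalid = skipped_invalid),
            class = "connectivity_matrix")
}

#' Binarize a connectivity matrix
#'
#' @param cm a [connectivity_matrix].
#' @param threshold minimum streamline count for an edge (default 1).
#' @return 0/1 integer matrix.
#' @export
binarize <- function(cm, threshold = 1L) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  out <- (cm$counts >= threshold) * 1L
  diag(out) <- 0L
  out
}

#' Toy endpoint parcellation for a synthetic substrate
#'
#' Labels the outer shell of the synthetic brain (where bundle endpoints
#' terminate, spanning the outer white matter and the cortical rim) by the
#' octant of the voxel position relative to the brain center; deep-GM blobs
#' get one extra parcel.  Intended as a small node set for connectivity
#' tests, not as anatomy, and assumes the generator's ellipsoidal frame.
#'
#' @param vf a [tissue_fraction_map] from [generate_numerical_brain].
#' @param shell_rho inner normalized-ellipsoid-radius bound of the shell.
#' @return integer 3D array of parcel labels (0 = none).
#' @export
toy_parcellation <- function(vf, shell_rho = 0.7) {
  stopifnot(inherits(vf, "tissue_fraction_map"))
  gs <- vf$grid_shape
  vs <- vf$voxel_size_mm
  ctr <- (gs - 1) / 2 * vs
  semi <- 0.45 * gs * vs                  # generator convention
  idx <- as.matrix(expand.grid(x = seq_len(gs[1]) - 1,
                               y = seq_len(gs[2]) - 1,
                               z = seq_len(gs[3]) - 1))
  w <- sweep(idx, 2, vs, `*`)
  rho <- sqrt(((w[, 1] - ctr[1]) / semi[1])^2 +
              ((w[, 2] - ctr[2]) / semi[2])^2 +
              ((w[, 3] - ctr[3]) / semi[3])^2)
  lab <- array(0L, dim = gs)
  shell <- rho >= shell_rho & array(vf$brain_mask, gs)
  oct <- 1L + (w[, 1] > ctr[1]) + 2L * (w[, 2] > ctr[2]) +
    4L * (w[, 3] > ctr[3])
  lab[array(shell, gs)] <- oct[shell]
  dgm <- vf$fractions[, , , "DGM"] >= 0.5
  lab[array(dgm, gs)] <- 9L
  lab
}
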