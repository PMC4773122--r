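# Simulated acquisition: gradient scheme generation, assembly of the ideal
# high-resolution volumes, and their degradation through k-space truncation,
# apodization, complex Gaussian noise and ideal-rectangle slice selection.

# --- gradient directions -----------------------------------------------------

# Antipodal electrostatic energy and its Euclidean gradient for unit rows y.
dir_energy_grad <- function(y) {
  n <- nrow(y)
  E <- 0
  g <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    dm <- sweep(y[(i + 1):n, , drop = FALSE], 2, y[i, ], `-`) * -1 # yi - yj
    sm <- sweep(y[(i + 1):n, , drop = FALSE], 2, y[i, ], `+`)      # yi + yj
    rdm <- sqrt(rowSums(dm^2)); rsm <- sqrt(rowSums(sm^2))
    E <- E + sum(1 / rdm + 1 / rsm)
    gi <- -dm / rdm^3 - sm / rsm^3
    g[i, ] <- g[i, ] + colSums(gi)
    g[(i + 1):n, ] <- g[(i + 1):n, ] + dm / rdm^3 - sm / rsm^3
  }
  list(E = E, g = g)
}

#' Electrostatically optimized diffusion gradient directions
#'
#' Minimizes the antipodal electrostatic repulsion energy
#' sum_(i<j) 1/|x_i - x_j| + 1/|x_i + x_j| on the unit sphere from a seeded
#' random start, to a projected-gradient norm below `tol`.
#'
#' @param n number of directions (>= 6).
#' @param seed RNG seed for the starting configuration.
#' @param tol convergence threshold on the Riemannian gradient norm.
#' @param max_rounds cap on successive BFGS polishing rounds.
#' @return n x 3 matrix of unit vectors (z >= 0 hemisphere, ordered by z).
#' @export
generate_directions <- function(n, seed = 1L, tol = 1e-8, max_rounds = 60L) {
  if (n < 6) stop("need at least 6 directions")
  x0 <- with_seed(seed, matrix(stats::rnorm(3 * n), n, 3))
  x0 <- x0 / sqrt(rowSums(x0^2))
  fn <- function(p) {
    y <- matrix(p, ncol = 3); y <- y / sqrt(rowSums(y^2))
    dir_energy_grad(y)$E
  }
  gr <- function(p) {
    x <- matrix(p, ncol = 3)
    nx <- sqrt(rowSums(x^2)); y <- x / nx
    eg <- dir_energy_grad(y)
    # chain rule through the row normalization: (I - y y^T) g / |x|
    g <- (eg$g - y * rowSums(eg$g * y)) / nx
    as.vector(g)
  }
  renorm <- function(p) {
    x <- matrix(p, ncol = 3)
    as.vector(x / sqrt(rowSums(x^2)))
  }
  p <- as.vector(x0)
  # quasi-Newton to the precision a value-based line search can reach ...
  for (round in 1:3) {
    fit <- stats::optim(p, fn, gr, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-16))
    p <- renorm(fit$par)
  }
  # ... then Newton polishing on the gradient itself (finite-difference
  # Hessian of the analytic projected gradient), which is not limited by
  # energy differences falling below machine epsilon.
  m <- length(p)
  h <- 1e-6
  gnorm <- sqrt(sum(gr(p)^2))
  for (round in seq_len(max_rounds)) {
    if (gnorm < tol) {
      x <- matrix(renorm(p), ncol = 3)
      flip <- x[, 3] < 0
      x[flip, ] <- -x[flip, ]
      return(x[order(x[, 3]), , drop = FALSE])
    }
    g <- gr(p)
    H <- matrix(0, m, m)
    for (j in seq_len(m)) {
      pj <- p; pj[j] <- pj[j] + h
      H[, j] <- (gr(pj) - g) / h
    }
    H <- (H + t(H)) / 2
    mu <- 1e-6 * mean(abs(diag(H)))
    step <- tryCatch(solve(H + mu * diag(m), g),
                     error = function(e) 1e-3 * g)
    p2 <- renorm(p - step)
    g2 <- sqrt(sum(gr(p2)^2))
    if (g2 < gnorm) { p <- p2; gnorm <- g2 } else {
      # damped retry, then give up through the round cap
      p2 <- renorm(p - 0.1 * step)
      g2 <- sqrt(sum(gr(p2)^2))
      if (g2 < gnorm) { p <- p2; gnorm <- g2 }
    }
  }
  stop(sprintf(paste0("direction optimization did not reach gradient norm ",
                      "%g after %d rounds (energy %.6f, |grad| %.3g)"),
               tol, max_rounds, fn(p), gnorm))
}

#' Multi-shell gradient scheme
#'
#' @param n_dirs directions per shell.
#' @param bvals shell b-values (s/mm^2), one entry per shell.
#' @param n_b0 number of leading b = 0 volumes (>= 1).
#' @param seed seed for the direction optimizer.
#' @return data.frame (class `gradient_scheme`) with columns `b_smm2`, `gx`,
#'   `gy`, `gz`; b = 0 rows carry a zero vector.
#' @export
gradient_scheme <- function(n_dirs = 60L, bvals = 1000, n_b0 = 6L, seed = 1L) {
  if (n_b0 < 1) stop("scheme needs at least one b = 0 volume")
  if (any(bvals <= 0)) stop("shell b-values must be > 0")
  dirs <- generate_directions(n_dirs, seed = seed)
  rows <- data.frame(b_smm2 = 0, gx = 0, gy = 0, gz = 0)[rep(1, n_b0), ]
  for (b in bvals)
    rows <- rbind(rows, data.frame(b_smm2 = b, gx = dirs[, 1],
                                   gy = dirs[, 2], gz = dirs[, 3]))
  rownames(rows) <- NULL
  structure(rows, class = c("gradient_scheme", "data.frame"), seed = seed)
}

# --- protocol ----------------------------------------------------------------

#' Acquisition protocol
#'
#' Bundles the gradient scheme, diffusion pulse timings, sequence timing,
#' resolution model and noise model.  The target voxel size is the native
#' size times an integer factor per axis.
#'
#' @param scheme a [gradient_scheme].
#' @param delta_s,Delta_s diffusion pulse duration / separation (s).
#' @param timing a [sequence_timing].
#' @param native_voxel_mm native (simulation) voxel size, default 0.7 mm.
#' @param factor integer downsampling factor per axis (scalar recycled).
#' @param filter `"none"`, `"fermi"` or `"hamming"`.
#' @param filter_params list; Fermi defaults: cutoff 0.9 k_max, width
#'   0.06 k_max.
#' @param snr target SNR (Inf for noiseless); see [simulate_acquisition] for
#'   the reference convention.
#' @param seed master seed for all noise streams.
#' @param noise_domain `"slice2d"` (multislice 2D spin echo) or `"volume3d"`.
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1).
#' @return list of class `protocol`.
#' @export
protocol <- function(scheme, delta_s = 12.9e-3, Delta_s = 21.8e-3,
                     timing = sequence_timing(57, 8800, B0_T = 3),
                     native_voxel_mm = 0.7, factor = 1L,
                     filter = c("none", "fermi", "hamming"),
                     filter_params = list(), snr = Inf, seed = 1L,
                     noise_domain = c("slice2d", "volume3d"),
                     gamma = GAMMA_H) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  filter <- match.arg(filter)
  noise_domain <- match.arg(noise_domain)
  if (length(factor) == 1) factor <- rep(factor, 3)
  if (any(factor != round(factor)) || any(factor < 1))
    stop("resolution factor must be a positive integer per axis")
  if (!is.infinite(snr) && snr <= 0) stop("snr must be > 0 or Inf")
  if (delta_s >= Delta_s) stop("delta must be shorter than Delta")
  structure(list(scheme = scheme, delta_s = delta_s, Delta_s = Delta_s,
                 gamma = gamma, timing = timing,
                 native_voxel_mm = native_voxel_mm,
                 factor = as.integer(factor), filter = filter,
                 filter_params = filter_params, snr = snr,
                 seed = as.integer(seed), noise_domain = noise_domain),
            class = "protocol")
}

#' Reference multi-shell phantom protocol preset
#'
#' 3 T, TR/TE = 8800/57 ms, delta = 12.9 ms, Delta = 21.8 ms, 6 b = 0 plus
#' 60 directions at the requested shell b-value (1000, 2500 or 10000
#' s/mm^2), native 0.7 mm with factor 1, 2 or 3 (0.7 / 1.4 / 2.1 mm).
#'
#' @param bval shell b-value in s/mm^2.
#' @param factor resolution factor (1, 2 or 3).
#' @param snr target SNR (Inf = noiseless).
#' @param seed master seed (directions and noise).
#' @return a [protocol].
#' @export
reference_protocol <- function(bval = 1000, factor = 1L, snr = Inf, seed = 1L) {
  protocol(gradient_scheme(60L, bvals = bval, n_b0 = 6L, seed = seed),
           delta_s = 12.9e-3, Delta_s = 21.8e-3,
           timing = sequence_timing(57, 8800, B0_T = 3),
           native_voxel_mm = 0.7, factor = factor, snr = snr, seed = seed)
}

pulse_for_volume <- function(proto, b_smm2) {
  if (b_smm2 == 0)
    pulse_params(proto$delta_s, proto$Delta_s, G_T_per_m = 0,
                 gamma = proto$gamma)
  else
    pulse_params(proto$delta_s, proto$Delta_s, b_smm2 = b_smm2,
                 gamma = proto$gamma)
}

# --- ideal volumes -----------------------------------------------------------

#' Ideal (noise- and artifact-free) DW volumes at native resolution
#'
#' Per voxel and volume: S_k(r) = S0(r) * sum_j v_j(r) A_jk(r), with the WM
#' attenuation averaged over the voxel's streamline segments and the DGM
#' anisotropic part taken as the WM powder average.  Fiber-free voxels with
#' v_WM > 0 fall back to the powder average (tallied).
#'
#' @param vf a [tissue_fraction_map].
#' @param field a [segment_direction_field] from [assign_segments].
#' @param models a [tissue_models] set.
#' @param proto a [protocol].
#' @param mrparams a [tissue_mr_params]; default chosen from the protocol's
#'   field strength.
#' @return 4D array `[x, y, z, volume]` at native resolution.
#' @export
ideal_dw_volumes <- function(vf, field, models = tissue_models(), proto,
                             mrparams = NULL) {
  stopifnot(inherits(proto, "protocol"))
  if (is.null(mrparams))
    mrparams <- tissue_mr_params(if (proto$timing$B0_T >= 2) "3T" else "1.5T")
  s0 <- s0_volume(vf, mrparams, proto$timing)
  sch <- proto$scheme
  nvol <- nrow(sch)
  out <- array(0, dim = c(vf$grid_shape, nvol))
  v <- vf$fractions
  orphan <- vf$fractions[, , , "WM"] > 0 & field$counts == 0
  n_orphan <- sum(orphan)
  if (n_orphan > 0)
    log_msg("ideal_dw_volumes: powder fallback in %d fiber-free WM voxel(s)",
            n_orphan)
  for (k in seq_len(nvol)) {
    b <- sch$b_smm2[k]
    if (b == 0) { out[, , , k] <- s0; next }
    pulse <- pulse_for_volume(proto, b)
    g <- c(sch$gx[k], sch$gy[k], sch$gz[k])
    A_csf <- attenuation_isotropic(models$CSF$MD, pulse$b_s_per_m2)
    A_cgm <- attenuation_isotropic(models$CGM$MD, pulse$b_s_per_m2)
    A_wm_powder <- powder_average(models$WM, pulse, g)
    A_dgm <- powder_average(models$DGM, pulse, g)
    A_wm <- wm_attenuation_map(field, models, pulse, g,
                               fallback_value = A_wm_powder)
    out[, , , k] <- s0 * (v[, , , "WM"] * A_wm + v[, , , "CGM"] * A_cgm +
                          v[, , , "DGM"] * A_dgm + v[, , , "CSF"] * A_csf)
  }
  attr(out, "powder_fallback_voxels") <- n_orphan
  out
}

# --- k-space machinery -------------------------------------------------------

fftshift_idx <- function(n) c((n - floor(n / 2) + 1):n,
                              seq_len(n - floor(n / 2)))
ifftshift_idx <- function(n) c((floor(n / 2) + 1):n, seq_len(floor(n / 2)))

# shifted-grid crop indices keeping the n/f lowest frequencies
crop_idx <- function(n, f) {
  n2 <- n %/% f
  c0 <- floor(n / 2) + 1
  (c0 - floor(n2 / 2)):(c0 + ceiling(n2 / 2) - 1)
}

# apodization window on the cropped, shifted k-space grid
apodization_window <- function(nx, ny, filter, params = list()) {
  kx <- (seq_len(nx) - (floor(nx / 2) + 1)) / (nx / 2)   # -1..1 of k_max
  ky <- (seq_len(ny) - (floor(ny / 2) + 1)) / (ny / 2)
  switch(filter,
    none = matrix(1, nx, ny),
    fermi = {
      cutoff <- params$cutoff %||% 0.9
      width <- params$width %||% 0.06
      kr <- sqrt(outer(kx^2, ky^2, `+`))
      1 / (1 + exp((kr - cutoff) / width))
    },
    hamming = {
      wx <- 0.54 + 0.46 * cos(pi * kx)
      wy <- 0.54 + 0.46 * cos(pi * ky)
      outer(wx, wy)
    },
    stop("unknown filter: ", filter))
}

#' Add complex Gaussian noise to a k-space slice stack
#'
#' The per-channel standard deviation `sigma_k` is calibrated by the caller
#' (see [kspace_sigma]) so that the image-domain noise SD after
#' reconstruction equals `reference_signal / SNR`.
#'
#' @param kvol complex 3D array (native k-space, slice stack).
#' @param snr_target target SNR (Inf = no-op).
#' @param reference_signal signal level defining the SNR.
#' @param seed RNG seed.
#' @param factor downsampling factor triple (enters the calibration).
#' @return complex array of the same shape.
#' @export
add_kspace_noise <- function(kvol, snr_target, reference_signal, seed = NULL,
                             factor = c(1L, 1L, 1L)) {
  if (is.infinite(snr_target)) return(kvol)
  if (snr_target <= 0) stop("snr_target must be > 0 or Inf")
  d <- dim(kvol)
  sigma_k <- kspace_sigma(reference_signal, snr_target, d[1:2], factor)
  with_seed(seed, {
    kvol + complex(real = stats::rnorm(prod(d), sd = sigma_k),
                   imaginary = stats::rnorm(prod(d), sd = sigma_k))
  })
}

#' k-space noise SD achieving a target image-domain noise SD
#'
#' With the unnormalized-FFT convention used here (inverse transform scaled
#' by the native matrix size), complex noise of SD sigma_k per channel in
#' native k-space yields an image-domain per-channel SD of
#' sigma_k * sqrt(Nx' Ny') / (Nx Ny) after central cropping, and a further
#' 1/sqrt(fz) from through-plane boxcar averaging.
#'
#' @param reference_signal,snr define the target image SD.
#' @param native_xy native in-plane matrix (length 2).
#' @param factor factor triple.
#' @return sigma_k (per channel).
#' @export
kspace_sigma <- function(reference_signal, snr, native_xy, factor) {
  target_sd <- reference_signal / snr
  nxp <- native_xy[1] %/% factor[1]
  nyp <- native_xy[2] %/% factor[2]
  target_sd * prod(native_xy) / sqrt(nxp * nyp) * sqrt(factor[3])
}

#' Degrade one volume through the simulated acquisition chain
#'
#' Pipeline per axial slice: forward FFT, optional complex Gaussian k-space
#' noise, central crop to the target in-plane matrix (truncation: Gibbs
#' ringing and partial volume), optional Fermi/Hamming apodization, inverse
#' FFT and magnitude; then through-plane boxcar averaging over `factor[3]`
#' adjacent native slices (ideal rectangular slice-selection profile).
#' Factor 1 without noise or filter is the identity up to round-off.
#'
#' @param vol real 3D array at native resolution.
#' @param proto a [protocol] (factor, filter, snr, noise seed domain).
#' @param sigma_k per-channel k-space noise SD (0 = noiseless); calibrate
#'   with [kspace_sigma].
#' @param seed noise stream seed.
#' @return real 3D array at target resolution.
#' @export
degrade <- function(vol, proto, sigma_k = 0, seed = NULL) {
  stopifnot(inherits(proto, "protocol"), length(dim(vol)) == 3)
  f <- proto$factor
  d <- dim(vol)
  if (any(d %% f != 0))
    stop("native matrix ", paste(d, collapse = "x"),
         " not divisible by factor ", paste(f, collapse = "x"))
  nxp <- d[1] %/% f[1]; nyp <- d[2] %/% f[2]
  ix <- crop_idx(d[1], f[1]); iy <- crop_idx(d[2], f[2])
  sx <- fftshift_idx(d[1]); sy <- fftshift_idx(d[2])
  ux <- ifftshift_idx(nxp); uy <- ifftshift_idx(nyp)
  win <- apodization_window(nxp, nyp, proto$filter, proto$filter_params)
  noise <- if (sigma_k > 0) {
    with_seed(seed, matrix(complex(real = stats::rnorm(prod(d), sd = sigma_k),
                                   imaginary = stats::rnorm(prod(d),
                                                            sd = sigma_k)),
                           d[1] * d[2], d[3]))
  } else NULL
  mag <- array(0, dim = c(nxp, nyp, d[3]))
  for (z in seq_len(d[3])) {
    K <- stats::fft(vol[, , z])
    if (!is.null(noise)) K <- K + matrix(noise[, z], d[1], d[2])
    Ks <- K[sx, sy][ix, iy] * win
    Kc <- Ks[ux, uy]
    img <- stats::fft(Kc, inverse = TRUE) / (d[1] * d[2])
    mag[, , z] <- Mod(img)
  }
  if (f[3] > 1) {
    nzp <- d[3] %/% f[3]
    out <- array(0, dim = c(nxp, nyp, nzp))
    for (z in seq_len(nzp)) {
      sl <- mag[, , ((z - 1) * f[3] + 1):(z * f[3]), drop = FALSE]
      out[, , z] <- apply(sl, c(1, 2), mean)
    }
    out
  } else mag
}

# --- full acquisition --------------------------------------------------------

#' Simulate a full DW acquisition
#'
#' Runs assign_segments -> s0_volume -> ideal_dw_volumes -> per-volume
#' degrade.  The SNR convention: SNR = (mean noiseless b = 0 signal over the
#' WM-dominant mask at target resolution) / (image-domain noise SD); each
#' volume receives an independent noise stream derived from the protocol
#' seed.
#'
#' @param vf a [tissue_fraction_map].
#' @param tract a [tractogram].
#' @param models a [tissue_models] set.
#' @param mrparams a [tissue_mr_params] (default from field strength).
#' @param proto a [protocol].
#' @return object of class `simulated_acquisition`: `data` (4D array at
#'   target resolution), `scheme`, `affine`, `protocol`, `provenance`.
#' @export
simulate_acquisition <- function(vf, tract, models = tissue_models(),
                                 mrparams = NULL, proto) {
  stopifnot(inherits(proto, "protocol"))
  if (is.null(mrparams))
    mrparams <- tissue_mr_params(if (proto$timing$B0_T >= 2) "3T" else "1.5T")
  field <- assign_segments(tract, vf)
  ideal <- ideal_dw_volumes(vf, field, models, proto, mrparams)
  nvol <- dim(ideal)[4]
  f <- proto$factor
  # SNR reference: mean noiseless b0 over the WM mask at target resolution
  sigma_k <- 0
  reference <- NA_real_
  if (!is.infinite(proto$snr)) {
    b0_idx <- which(proto$scheme$b_smm2 == 0)[1]
    b0_t <- degrade(ideal[, , , b0_idx], proto)
    wm_t <- block_mean(vf$fractions[, , , "WM"], f) >= 0.5
    if (!any(wm_t)) stop("cannot calibrate SNR: empty WM mask at target res")
    reference <- mean(b0_t[wm_t])
    sigma_k <- kspace_sigma(reference, proto$snr, dim(ideal)[1:2], f)
  }
  seeds <- derive_seeds(proto$seed, nvol)
  dims_t <- dim(ideal)[1:3] %/% f
  data <- array(0, dim = c(dims_t, nvol))
  for (k in seq_len(nvol))
    data[, , , k] <- degrade(ideal[, , , k], proto, sigma_k = sigma_k,
                             seed = seeds[k])
  affine_t <- vf$affine
  affine_t[1:3, 1:3] <- affine_t[1:3, 1:3] %*% diag(f)
  # voxel centers shift when grouping f native voxels into one
  affine_t[1:3, 4] <- affine_t[1:3, 4] +
    vf$affine[1:3, 1:3] %*% ((f - 1) / 2)
  structure(list(data = data, scheme = proto$scheme, affine = affine_t,
                 protocol = proto,
                 provenance = list(
                   seed = proto$seed, volume_seeds = seeds,
                   snr = proto$snr, sigma_k = sigma_k,
                   snr_reference = reference, factor = f,
                   filter = proto$filter,
                   dropped_segments = field$dropped,
                   powder_fallback_voxels =
                     attr(ideal, "powder_fallback_voxels"))),
            class = "simulated_acquisition")
}

#' @export
print.simulated_acquisition <- function(x, ...) {
  d <- dim(x$data)
  cat("<simulated_acquisition>", d[4], "volumes of",
      paste(d[1:3], collapse = "x"), "voxels; SNR",
      x$protocol$snr, "\n")
  invisible(x)
}

# block average a 3D array by integer factors (through-plane/in-plane
# partial-volume reference, used for masks and oracles)
block_mean <- function(arr, f) {
  d <- dim(arr)
  stopifnot(all(d %% f == 0))
  dt <- d %/% f
  out <- array(0, dim = dt)
  for (i in 0:(f[1] - 1)) for (j in 0:(f[2] - 1)) for (k in 0:(f[3] - 1)) {
    out <- out + arr[seq(1 + i, d[1], by = f[1]),
                     seq(1 + j, d[2], by = f[2]),
                     seq(1 + k, d[3], by = f[3])]
  }
  out / prod(f)
}

#' Write an acquisition as NIfTI + FSL bval/bvec + provenance JSON
#'
#' @param acq a [simulated_acquisition].
#' @param prefix output path prefix; writes `<prefix>.nii`, `<prefix>.bval`,
#'   `<prefix>.bvec`, `<prefix>.json`.
#' @return named character vector of the written paths, invisibly.
#' @export
write_acquisition <- function(acq, prefix) {
  stopifnot(inherits(acq, "simulated_acquisition"))
  paths <- c(nii = paste0(prefix, ".nii"), bval = paste0(prefix, ".bval"),
             bvec = paste0(prefix, ".bvec"), json = paste0(prefix, ".json"))
  write_nifti(acq$data, paths["nii"], affine = acq$affine)
  writeLines(paste(acq$scheme$b_smm2, collapse = " "), paths["bval"])
  bv <- rbind(acq$scheme$gx, acq$scheme$gy, acq$scheme$gz)
  writeLines(apply(bv, 1, paste, collapse = " "), paths["bvec"])
  prov <- acq$provenance
  prov$scheme_seed <- attr(acq$scheme, "seed")
  jsonlite::write_json(prov, paths["json"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
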