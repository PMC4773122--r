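# Anatomical (non-diffusion-weighted) signal: equilibrium magnetization,
# spin-echo relaxation weighting, and the volume-fraction-weighted S0 map.

#' Scanner-dependent tissue MR constants
#'
#' Built-in presets for 1.5 T and 3 T (proton density relative to CSF = 1,
#' T1 and T2 in ms).  DGM is not tabulated separately and is mapped onto the
#' GM column (flagged via the `dgm_as_gm` attribute).
#'
#' @param field `"3T"` or `"1.5T"`.
#' @return data.frame with rows WM, CGM, DGM, CSF and columns PD, T1_ms,
#'   T2_ms; class `tissue_mr_params`.
#' @export
tissue_mr_params <- function(field = c("3T", "1.5T")) {
  field <- match.arg(field)
  tab <- if (field == "3T") {
    data.frame(row.names = c("WM", "GM", "CSF"),
               PD = c(0.77, 0.86, 1), T1_ms = c(832, 1331, 3700),
               T2_ms = c(44, 51, 500))
  } else {
    data.frame(row.names = c("WM", "GM", "CSF"),
               PD = c(0.77, 0.86, 1), T1_ms = c(500, 833, 2569),
               T2_ms = c(70, 83, 329))
  }
  out <- tab[c("WM", "GM", "GM", "CSF"), ]
  rownames(out) <- TISSUES
  stopifnot(all(out$T1_ms > out$T2_ms), all(out$T2_ms > 0),
            all(out$PD > 0 & out$PD <= 1))
  structure(out, class = c("tissue_mr_params", "data.frame"),
            field = field, dgm_as_gm = TRUE)
}

#' Sequence timing and static-field parameters
#'
#' @param TE_ms,TR_ms echo and repetition time (ms), `0 < TE < TR`.
#' @param B0_T static field (T).
#' @param Ts_K sample temperature (K); default body temperature.
#' @return list of class `sequence_timing`.
#' @export
sequence_timing <- function(TE_ms, TR_ms, B0_T = 3, Ts_K = 310) {
  if (TE_ms <= 0 || TE_ms >= TR_ms)
    stop("need 0 < TE < TR (got TE = ", TE_ms, ", TR = ", TR_ms, " ms)")
  if (B0_T <= 0 || Ts_K <= 0) stop("B0 and sample temperature must be > 0")
  structure(list(TE_ms = TE_ms, TR_ms = TR_ms, B0_T = B0_T, Ts_K = Ts_K),
            class = "sequence_timing")
}

#' Equilibrium magnetization
#'
#' M = PD * (gamma h / 2 pi)^2 * B0 / (4 Kb Ts): linear in proton density
#' and field strength.  Absolute units are arbitrary; only ratios between
#' tissues are meaningful.
#'
#' @param PD relative proton density.
#' @param timing a [sequence_timing] (supplies B0 and Ts).
#' @return magnetization (arbitrary units).
#' @export
magnetization <- function(PD, timing) {
  stopifnot(inherits(timing, "sequence_timing"))
  if (timing$B0_T <= 0 || timing$Ts_K <= 0) stop("B0 and Ts must be > 0")
  PD * (GAMMA_H * PLANCK_H / (2 * pi))^2 * timing$B0_T /
    (4 * BOLTZMANN_KB * timing$Ts_K)
}

#' Spin-echo steady-state signal of a pure tissue
#'
#' S0 = M * exp(-TE/T2) * (1 - exp(-TR/T1)).  With `normalize = TRUE`
#' (default) the arbitrary magnetization scale is fixed so that a pure-CSF
#' voxel in the limit TE -> 0, TR -> Inf reads 1 (i.e. M reduces to PD).
#'
#' @param tissue one of `"WM"`, `"CGM"`, `"DGM"`, `"CSF"`.
#' @param params a [tissue_mr_params] table.
#' @param timing a [sequence_timing].
#' @param normalize use the CSF-normalized signal scale.
#' @return scalar signal.
#' @export
spin_echo_signal <- function(tissue, params, timing, normalize = TRUE) {
  tissue <- match.arg(tissue, TISSUES)
  stopifnot(inherits(params, "tissue_mr_params"),
            inherits(timing, "sequence_timing"))
  p <- params[tissue, ]
  M <- if (normalize) p$PD else magnetization(p$PD, timing)
  M * exp(-timing$TE_ms / p$T2_ms) * (1 - exp(-timing$TR_ms / p$T1_ms))
}

#' Anatomical S0 volume (volume-fraction-weighted spin-echo signal)
#'
#' @param vf a [tissue_fraction_map].
#' @param params a [tissue_mr_params] table.
#' @param timing a [sequence_timing].
#' @return 3D array; zero outside the brain mask.
#' @export
s0_volume <- function(vf, params, timing) {
  stopifnot(inherits(vf, "tissue_fraction_map"))
  s0j <- vapply(TISSUES, spin_echo_signal, 0, params = params,
                timing = timing)
  out <- array(0, dim = vf$grid_shape)
  for (j in seq_along(TISSUES))
    out <- out + array(vf$fractions[, , , j], dim = vf$grid_shape) * s0j[j]
  out[!vf$brain_mask] <- 0
  out
}
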