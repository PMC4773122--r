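# Analytic per-tissue diffusion attenuation models.
#
# WM is a two-compartment "zeppelin-cylinder": intra-axonal water as a
# restricted cylinder (Gaussian phase distribution, Van Gelderen form) and
# extra-axonal water as an axially symmetric tensor (zeppelin).  CGM and CSF
# are isotropic tensors; DGM is a 20/80 mixture of the WM and CGM models.
# All attenuations are normalized (A = 1 at b = 0) and antipodally symmetric.

#' Pulsed-gradient spin-echo pulse parameters
#'
#' Either the gradient amplitude `G_T_per_m` or a target `b_smm2` must be
#' given; the other is derived through the Stejskal-Tanner relation
#' b = gamma^2 G^2 delta^2 (Delta - delta/3).
#'
#' @param delta_s gradient pulse duration delta (s).
#' @param Delta_s pulse separation Delta (s); must exceed `delta_s`.
#' @param G_T_per_m gradient amplitude (T/m).
#' @param b_smm2 target b-value (s/mm^2); used to solve for G.
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1).
#' @return object of class `pulse_params` with fields `delta_s`, `Delta_s`,
#'   `G_T_per_m`, `gamma`, `b_s_per_m2`.
#' @export
pulse_params <- function(delta_s, Delta_s, G_T_per_m = NULL, b_smm2 = NULL,
                         gamma = GAMMA_H) {
  if (delta_s >= Delta_s)
    stop("gradient duration delta must be shorter than the separation Delta")
  if (delta_s <= 0 || Delta_s <= 0 || gamma <= 0)
    stop("pulse timings and gamma must be positive")
  if (is.null(G_T_per_m)) {
    if (is.null(b_smm2)) stop("provide either G_T_per_m or b_smm2")
    G_T_per_m <- gradient_for_b(b_smm2, delta_s, Delta_s, gamma)
  }
  if (G_T_per_m < 0) stop("gradient amplitude must be >= 0")
  obj <- structure(list(delta_s = delta_s, Delta_s = Delta_s,
                        G_T_per_m = G_T_per_m, gamma = gamma),
                   class = "pulse_params")
  obj$b_s_per_m2 <- b_value(obj)
  obj
}

#' Stejskal-Tanner b-value (SI, s/m^2)
#'
#' @param pulse a [pulse_params].
#' @return b = gamma^2 G^2 delta^2 (Delta - delta/3) in s/m^2.
#' @export
b_value <- function(pulse) {
  stopifnot(inherits(pulse, "pulse_params"))
  with(pulse, gamma^2 * G_T_per_m^2 * delta_s^2 * (Delta_s - delta_s / 3))
}

#' Gradient amplitude achieving a requested b-value
#'
#' @param b_smm2 b-value in s/mm^2.
#' @inheritParams pulse_params
#' @return G in T/m.
#' @export
gradient_for_b <- function(b_smm2, delta_s, Delta_s, gamma = GAMMA_H) {
  if (b_smm2 < 0) stop("b-value must be >= 0")
  if (delta_s >= Delta_s) stop("delta must be shorter than Delta")
  sqrt(b_smm2_to_si(b_smm2) / (gamma^2 * delta_s^2 * (Delta_s - delta_s / 3)))
}

#' Isotropic (free) diffusion attenuation
#'
#' @param MD mean diffusivity (m^2/s).
#' @param b_si b-value (s/m^2).
#' @return exp(-b * MD), direction-independent.
#' @export
attenuation_isotropic <- function(MD, b_si) {
  if (any(MD <= 0)) stop("MD must be > 0")
  if (any(b_si < 0)) stop("b must be >= 0")
  exp(-b_si * MD)
}

#' Zeppelin (axially symmetric tensor) attenuation
#'
#' @param d_par,d_perp parallel / perpendicular diffusivities (m^2/s),
#'   `d_par >= d_perp > 0`.
#' @param fiber_dir,grad_dir unit 3-vectors (checked to 1e-6).
#' @param b_si b-value (s/m^2).
#' @return exp(-b (d_perp + (d_par - d_perp) (g.n)^2)).
#' @export
attenuation_zeppelin <- function(d_par, d_perp, fiber_dir, grad_dir, b_si) {
  if (d_perp <= 0 || d_par < d_perp)
    stop("need d_par >= d_perp > 0")
  fiber_dir <- unit_vector(fiber_dir, what = "fiber_dir")
  grad_dir <- unit_vector(grad_dir, what = "grad_dir")
  ct2 <- sum(fiber_dir * grad_dir)^2
  exp(-b_si * (d_perp + (d_par - d_perp) * ct2))
}

# --- GPD restricted cylinder -------------------------------------------------

# First n roots of J1'(x) = 0, computed once and cached.  J1'(x) =
# (J0(x) - J2(x)) / 2; roots are ~pi apart beyond the first (1.8412...).
.dwiphantom_cache <- new.env(parent = emptyenv())

bessel_j1prime_roots <- function(n = 20L) {
  key <- as.character(n)
  cached <- .dwiphantom_cache[[paste0("j1p", key)]]
  if (!is.null(cached)) return(cached)
  f <- function(x) besselJ(x, 0) - besselJ(x, 2)
  xs <- seq(1, (n + 2) * pi, by = 0.05)
  fv <- f(xs)
  sgn <- which(fv[-1] * fv[-length(fv)] < 0)
  roots <- vapply(sgn, function(i)
    stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-14)$root, 0)
  roots <- roots[seq_len(n)]
  .dwiphantom_cache[[paste0("j1p", key)]] <- roots
  roots
}

# Van Gelderen GPD sum S(D, R, delta, Delta): perpendicular attenuation is
# exp(-2 gamma^2 G_perp^2 * S).  Series over roots alpha_m = mu_m / R of
# J1'(mu) = 0.  Starts from `n_roots` terms and extends (terms fall off as
# mu^-6) until the last term is below `tol` of the running total; errors
# with the truncation bound if `root_cap` is reached first.
gpd_sum <- function(D, R, delta, Delta, n_roots = 20L, tol = 1e-10,
                    root_cap = 200L) {
  n <- n_roots
  repeat {
    mu <- bessel_j1prime_roots(n)
    a2 <- (mu / R)^2                     # alpha_m^2
    Da2 <- D * a2
    num <- 2 * Da2 * delta - 2 +
      2 * exp(-Da2 * delta) + 2 * exp(-Da2 * Delta) -
      exp(-Da2 * (Delta - delta)) - exp(-Da2 * (Delta + delta))
    terms <- num / (D^2 * a2^3 * (a2 * R^2 - 1))
    total <- sum(terms)
    if (total <= 0 || abs(terms[n]) <= tol * abs(total)) return(total)
    if (n >= root_cap)
      stop(sprintf(paste0("GPD series not converged at the %d-root cap ",
                          "(truncation bound %.3g of the sum > %.1g)"),
                   root_cap, abs(terms[n]) / abs(total), tol))
    n <- min(root_cap, n * 2L)
  }
}

#' Restricted-cylinder (GPD) attenuation
#'
#' Separable product of free diffusion along the cylinder axis and
#' Gaussian-phase-distribution restricted diffusion across it (Van Gelderen
#' form, series over the roots of the derivative of the first-order Bessel
#' function, truncated at 20 roots with relative tolerance 1e-10).
#'
#' @param d intrinsic diffusivity (m^2/s).
#' @param R cylinder radius (m).
#' @param fiber_dir,grad_dir unit 3-vectors.
#' @param pulse a [pulse_params].
#' @return attenuation in (0, 1].
#' @export
attenuation_cylinder <- function(d, R, fiber_dir, grad_dir, pulse) {
  if (d <= 0 || R <= 0) stop("need d > 0 and R > 0")
  stopifnot(inherits(pulse, "pulse_params"))
  fiber_dir <- unit_vector(fiber_dir, what = "fiber_dir")
  grad_dir <- unit_vector(grad_dir, what = "grad_dir")
  ct2 <- sum(fiber_dir * grad_dir)^2
  b <- pulse$b_s_per_m2
  A_par <- exp(-b * ct2 * d)
  G_perp2 <- pulse$G_T_per_m^2 * (1 - ct2)
  A_perp <- if (G_perp2 <= 0 || pulse$G_T_per_m == 0) 1 else
    exp(-2 * pulse$gamma^2 * G_perp2 *
          gpd_sum(d, R, pulse$delta_s, pulse$Delta_s))
  A_par * A_perp
}

# --- tissue presets ----------------------------------------------------------

compartment_isotropic <- function(MD) {
  stopifnot(MD > 0)
  structure(list(kind = "isotropic", MD = MD), class = "compartment_spec")
}
compartment_zeppelin <- function(d_par, d_perp) {
  stopifnot(d_par >= d_perp, d_perp > 0)
  structure(list(kind = "zeppelin", d_par = d_par, d_perp = d_perp),
            class = "compartment_spec")
}
compartment_cylinder <- function(d, R) {
  stopifnot(d > 0, R > 0)
  structure(list(kind = "cylinder", d = d, R = R), class = "compartment_spec")
}
compartment_mixture <- function(specs, weights) {
  stopifnot(length(specs) == length(weights),
            all(weights >= 0), abs(sum(weights) - 1) < 1e-12)
  structure(list(kind = "mixture", specs = specs, weights = weights),
            class = "compartment_spec")
}

#' Built-in tissue diffusion models
#'
#' The default parameter set (in-vivo human values): WM is a mixture of a
#' restricted cylinder (59% of the signal, d = 1.49e-9 m^2/s, radius
#' 4.8e-6 m) and a zeppelin (41%, parallel 1.49e-9, perpendicular
#' 0.72e-9 m^2/s); CGM and CSF are isotropic with MD 0.83e-9 and 3.19e-9
#' m^2/s; DGM mixes the full WM model (20%) with CGM (80%).
#'
#' @param wm_cyl_frac,wm_d,wm_R,wm_zep_perp,cgm_MD,csf_MD,dgm_wm_frac
#'   overridable parameters (SI units).
#' @return named list of `compartment_spec`s, class `tissue_model_set`.
#' @export
tissue_models <- function(wm_cyl_frac = 0.59, wm_d = 1.49e-9, wm_R = 4.8e-6,
                          wm_zep_perp = 0.72e-9, cgm_MD = 0.83e-9,
                          csf_MD = 3.19e-9, dgm_wm_frac = 0.20) {
  wm <- compartment_mixture(
    list(compartment_cylinder(wm_d, wm_R),
         compartment_zeppelin(wm_d, wm_zep_perp)),
    c(wm_cyl_frac, 1 - wm_cyl_frac))
  cgm <- compartment_isotropic(cgm_MD)
  structure(list(WM = wm, CGM = cgm,
                 DGM = compartment_mixture(list(wm, cgm),
                                           c(dgm_wm_frac, 1 - dgm_wm_frac)),
                 CSF = compartment_isotropic(csf_MD)),
            class = "tissue_model_set")
}

attenuation_spec <- function(spec, pulse, grad_dir, fiber_dir = NULL) {
  switch(spec$kind,
    isotropic = attenuation_isotropic(spec$MD, pulse$b_s_per_m2),
    zeppelin = {
      if (is.null(fiber_dir)) stop("zeppelin needs a fiber direction")
      attenuation_zeppelin(spec$d_par, spec$d_perp, fiber_dir, grad_dir,
                           pulse$b_s_per_m2)
    },
    cylinder = {
      if (is.null(fiber_dir)) stop("cylinder needs a fiber direction")
      attenuation_cylinder(spec$d, spec$R, fiber_dir, grad_dir, pulse)
    },
    mixture = sum(spec$weights * vapply(spec$specs, attenuation_spec, 0,
                                        pulse = pulse, grad_dir = grad_dir,
                                        fiber_dir = fiber_dir)),
    stop("unknown compartment kind: ", spec$kind))
}

#' Powder (orientation) average of an anisotropic model
#'
#' Numerical average over a fixed 300-direction antipodal set; used for
#' DGM's anisotropic component and as a fallback for WM voxels without
#' streamline orientations.
#'
#' @param spec a compartment spec.
#' @param pulse a [pulse_params].
#' @param grad_dir unit gradient direction (result is independent of it for
#'   a uniform orientation distribution; it fixes the evaluation geometry).
#' @param n_dirs size of the fixed direction set.
#' @return scalar attenuation.
#' @export
powder_average <- function(spec, pulse, grad_dir = c(0, 0, 1), n_dirs = 300L) {
  dirs <- fibonacci_hemisphere(n_dirs)
  mean(apply(dirs, 1, function(n)
    attenuation_spec(spec, pulse, grad_dir, fiber_dir = n)))
}

#' Tissue attenuation (Eq. of the multi-compartment model)
#'
#' @param tissue one of `"WM"`, `"CGM"`, `"DGM"`, `"CSF"`.
#' @param models a [tissue_models] set.
#' @param pulse a [pulse_params].
#' @param grad_dir unit gradient direction.
#' @param fiber_dir unit fiber direction; required for WM/DGM unless
#'   `powder_fallback = TRUE`.
#' @param powder_fallback orientation-average the anisotropic part when no
#'   fiber direction is available.
#' @return scalar attenuation in (0, 1].
#' @export
attenuation_tissue <- function(tissue, models = tissue_models(), pulse,
                               grad_dir, fiber_dir = NULL,
                               powder_fallback = FALSE) {
  tissue <- match.arg(tissue, TISSUES)
  spec <- models[[tissue]]
  needs_dir <- tissue %in% c("WM", "DGM")
  if (needs_dir && is.null(fiber_dir)) {
    if (!powder_fallback)
      stop(tissue, " attenuation requires fiber_dir (or powder_fallback)")
    return(powder_average(spec, pulse, grad_dir))
  }
  attenuation_spec(spec, pulse, grad_dir, fiber_dir)
}
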