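---
title: "Simulating ground-truth diffusion MRI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ground-truth diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwiphantom)
```

## What the package computes

`dwiphantom` turns a *known* brain substrate — per-voxel volume fractions of
four tissue classes (WM, cortical GM, deep GM, CSF) and a streamline
tractogram in world millimeters — into multi-shell diffusion-weighted image
volumes through three physical layers:

1. **Relaxometry.** Each tissue's non-diffusion-weighted signal is the
   spin-echo steady state `S0_j = M_j exp(-TE/T2_j)(1 - exp(-TR/T1_j))`,
   with equilibrium magnetization proportional to `PD_j B0 / T_s`. Voxels
   mix linearly through the volume fractions. Built-in constants cover
   1.5 T and 3 T (e.g. WM at 3 T: PD 0.77, T1 832 ms, T2 44 ms).
2. **Diffusion attenuation.** Normalized per-tissue attenuations multiply
   the fractions inside the same linear mixture. CSF and cortical GM are
   isotropic (`exp(-b MD)`, MD 3.19 and 0.83 × 10⁻⁹ m²/s). WM is a
   zeppelin–cylinder pair: 59% restricted cylinder (d = 1.49 × 10⁻⁹ m²/s,
   R = 4.8 µm) and 41% zeppelin (1.49 / 0.72 × 10⁻⁹ m²/s). In each voxel
   the single-fiber WM model is evaluated at the direction of every
   tractogram segment assigned to the voxel and arithmetically averaged.
   Deep GM is 20% WM model + 80% cortical GM.
3. **Acquisition.** Ideal volumes are simulated at the native 0.7 mm grid,
   then degraded per axial slice: forward FFT, complex Gaussian k-space
   noise, central k-space crop to the target matrix, optional Fermi or
   Hamming apodization, inverse FFT, magnitude; through-plane resolution is
   reduced by boxcar-averaging adjacent slices (an ideal rectangular slice
   profile). The result carries Gibbs ringing, partial volume and Rician
   noise with the correct spatial statistics.

## Tunable parameters that matter

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| δ, Δ | 12.9, 21.8 | ms | reference protocol's pulse timings |
| b per shell | 1000 / 2500 / 10000 | s/mm² | reference shells; G solved from the Stejskal–Tanner relation |
| TE, TR | 57, 8800 | ms | reference spin-echo timing at 3 T |
| native voxel | 0.7 | mm | substrate resolution; targets are integer multiples (1.4, 2.1) |
| SNR | Inf (off) | — | mean noiseless b=0 over the WM mask at target resolution ÷ image-domain noise SD |
| directions | 60 per shell + 6 b=0 | — | antipodal electrostatic repulsion, seeded |
| γ | 2.6752219e8 | rad s⁻¹ T⁻¹ | hydrogen |
| T_s | 310 | K | body temperature; only enters as a scale |

Units are SI internally (m, s, T); the user-facing b-value is s/mm² with
conversion at the boundary (1 s/mm² = 10⁶ s/m²).

## The restricted cylinder

Perpendicular to the axis the cylinder uses the Gaussian-phase-distribution
(Van Gelderen) expression: `A_perp = exp(-2 γ² G_perp² S)` with `S` a series
over the roots of `J₁'(x) = 0`. The series starts at 20 roots and extends
(terms fall off as the sixth power of the root) until the last term is below
10⁻¹⁰ of the running total, erroring at a 200-root cap; at the default WM
radius ~40 roots certify the tolerance. Parallel to the axis diffusion is
free, so the two factors separate and the model is Gaussian in the
perpendicular gradient component.

GPD is itself an approximation. Against an exact Monte-Carlo random walk
(reflecting cylinder wall, phase accumulated under both pulses) we measured
a model error of +1.2 × 10⁻³ in attenuation at the WM radius by
b = 1000 s/mm², growing with gradient strength. The oracle acceptance test
therefore compares GPD and the walk on a 3 × 3 grid (R ∈ {2, 3.5, 4.8} µm ×
b ∈ {125, 250, 500} s/mm²) where the model error stays within ~1 SE of the
10⁵-walker oracle: a tighter grid would test the *approximation*, not the
implementation. At the b = 2500 and 10000 s/mm² shells the simulated WM
signal inherits this (documented) GPD bias.

## The synthetic substrate: what it emulates, what it does not

The generator stands in for segmentation- and tractography-derived inputs.
It emulates the *features that make DW processing hard*: crossing, bending
and kissing bundle configurations at configurable angle and curvature, a
cortical GM rim, a CSF cavity with a sharp high-contrast boundary (the
Gibbs test bed), deep-GM blobs, and partial-volume fractions obtained by
3 × 3 × 3 sub-voxel occupancy rasterization (no standard exists for
discretizing sub-voxel tissue fractions, so occupancy counting is this
package's documented choice).

Deliberate simplifications a green test does **not** rule out:

- Bundles are tubes around analytic centerlines; real fasciculi fan,
  disperse and vary in caliber. No fiber-dispersion model is included.
- Streamlines fill the inner 70% of each tube cross-section and stop one
  step short of the end caps. This guarantees the generator contract that
  every non-terminal streamline point lies in a WM-dominant voxel, at the
  cost of an outer WM shell without explicit orientations; those voxels
  (and deep-GM blobs, which deliberately contain no streamlines) use the
  powder (orientation) average of the WM model, computed over a fixed
  300-direction antipodal set. Real boundary voxels contain oriented,
  dispersed fibers instead.
- The interior that no bundle claims defaults to cortical-GM-like isotropy
  rather than unlabeled deep WM.
- Tissue homogeneity: one parameter set per class, no regional variation.

## Numerical choices

- **Segment assignment**: a segment belongs to the voxel containing its
  midpoint (half-up tie-break on voxel boundaries). The 0.7 mm step never
  exceeds the voxel size in the supported protocols, so midpoint and
  face-splitting assignment differ by at most one voxel per segment.
- **Direction schemes**: BFGS on the antipodal electrostatic energy, then
  Newton polishing on the analytic projected gradient (a value-based line
  search stalls near 10⁻⁵ because energy differences fall below machine
  epsilon); converged when the Riemannian gradient norm is < 10⁻⁸.
- **Tensor fit**: ordinary least squares on log-signals in s/mm² units (the
  SI-unit design matrix is numerically singular against the intercept);
  the tensor is converted back to m²/s afterwards.
- **k-space bookkeeping**: the inverse FFT is normalized by the *native*
  matrix size, which makes factor-1 degradation the identity to round-off
  and preserves the DC level (a constant image stays constant at every
  factor). Central cropping keeps frequencies −⌊N′/2⌋ … ⌈N′/2⌉−1.
- **Noise calibration**: complex Gaussian noise of SD σ_k per channel is
  added once per volume in native per-slice k-space ("before the smoothing
  step"); σ_k is chosen so the image-domain SD at target resolution equals
  reference/SNR, including the 1/√factor_z gain of through-plane averaging.
  Whether the original work added noise per-slice or volumetrically is not
  stated; for i.i.d. complex Gaussian noise the two are statistically
  identical after this pipeline, and a `noise_domain` switch records the
  convention.
- **Signal scale**: arbitrary; normalized so a pure-CSF voxel at TE → 0,
  TR → ∞ reads 1. Only tissue ratios are physically meaningful.
- **Degenerate inputs**: fractions outside [0,1] beyond tolerance, 3-class
  fraction files, non-unit direction vectors, δ ≥ Δ, TE ≥ TR, non-integer
  resolution factors and coordinate-ambiguous streamline files all error
  with diagnostics rather than guessing.

## Design decisions where the design was open

- **DGM orientation**: whether the 20% WM component of deep GM follows
  local streamline directions or an orientation average is not specified
  anywhere; the powder average is the default (deep-GM blobs carry no
  synthetic streamlines), and voxel-level orientations remain available
  through the generic attenuation API.
- **Connectivity semantics**: streamline counting is endpoint-based (a
  streamline connects the parcels of its two endpoints, once), with
  intra-parcel and out-of-grid streamlines tallied separately;
  binarization thresholds at ≥ 1 by default.
- **TRK support was dropped**: the TRK format's voxel-order and
  corner/center conventions could not be cross-validated against any
  available reference implementation, and a silently wrong convention is
  worse than an explicit unsupported-format error. TCK — which is defined
  in world mm, the package's native frame — is fully supported.
- **Config format**: JSON (nested keys mirroring the module boundaries),
  with file digests and all seeds recorded in a run manifest so identical
  configs reproduce bit-identical outputs.

## Known limitations

- No EPI distortions, eddy currents, motion or pulsation; single-coil
  magnitude reconstruction only.
- The GPD bias at high b (above) and the absence of fiber dispersion bound
  the realism of the strongest shell.
- DGM relaxometry constants are not tabulated separately at either field
  strength and are mapped onto the GM column (flagged in the preset).
- Graph metrics beyond connectivity-matrix construction and binarization
  are out of scope; export the matrices to a graph toolbox instead.
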