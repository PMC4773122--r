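test_that("direction schemes are optimal, distinct and deterministic", {
  d6 <- generate_directions(6, seed = 2)
  expect_equal(rowSums(d6^2), rep(1, 6), tolerance = 1e-12)
  # energy matches the independent multi-start oracle
  expect_equal(dir_energy(d6), min_energy_oracle(6, restarts = 100),
               tolerance = 1e-4)
  # distinct points: positive minimum antipodal angle
  cosang <- abs(d6 %*% t(d6))[upper.tri(diag(6))]
  expect_gt(min(acos(pmin(1, cosang))), 0)
  expect_identical(d6, generate_directions(6, seed = 2))
  expect_error(generate_directions(4), "at least 6")
})

test_that("gradient schemes carry b0 rows and unit directions", {
  sch <- tiny_scheme(n_dirs = 12, bval = 1000, n_b0 = 2)
  expect_equal(nrow(sch), 14)
  expect_equal(sum(sch$b_smm2 == 0), 2)
  g <- as.matrix(sch[sch$b_smm2 > 0, c("gx", "gy", "gz")])
  expect_equal(unname(rowSums(g^2)), rep(1, 12), tolerance = 1e-10)
  expect_error(gradient_scheme(12, 1000, n_b0 = 0), "at least one b = 0")
})

test_that("ideal volumes obey the signal model", {
  sb <- small_substrate()
  models <- tissue_models()
  proto <- trim_protocol(reference_protocol(bval = 1000, seed = 2), n = 3)
  field <- assign_segments(sb$tractogram, sb$vf)
  mrp <- tissue_mr_params("3T")
  ideal <- ideal_dw_volumes(sb$vf, field, models, proto, mrp)
  s0 <- s0_volume(sb$vf, mrp, proto$timing)
  # b0 volume equals S0 exactly
  expect_equal(ideal[, , , 1], s0)
  # attenuation bounded by S0
  for (k in 2:4) {
    expect_true(all(ideal[, , , k] <= s0 + 1e-12))
    expect_true(all(ideal[, , , k] >= 0))
  }
  # pure-CSF voxel: S0 * exp(-b MD) regardless of direction
  csf <- which(sb$vf$fractions[, , , "CSF"] == 1 &
                 array(sb$vf$brain_mask, sb$vf$grid_shape))[1]
  expect_false(is.na(csf))
  v1 <- ideal[, , , 2][csf]; v2 <- ideal[, , , 3][csf]
  expect_equal(v1, s0[csf] * exp(-3.19), tolerance = 1e-9)
  expect_equal(v2, v1, tolerance = 1e-12)
  # half WM / half CSF voxel with a single fiber: two-term hand sum
  fr <- array(0, dim = c(4, 4, 4, 4))
  fr[, , , 1] <- 0.5; fr[, , , 4] <- 0.5
  vf2 <- tissue_fraction_map(fr, affine = diag(4))
  sl <- list(cbind(c(0.6, 1.4), 2, 2))    # one x-fiber through (1,2,2)
  f2 <- assign_segments(tractogram(sl, nominal_step_mm = 0.8), vf2)
  p2 <- trim_protocol(reference_protocol(bval = 1000, seed = 2), n = 1)
  p2$scheme[2, c("gx", "gy", "gz")] <- c(1, 0, 0)   # g parallel to fiber
  id2 <- ideal_dw_volumes(vf2, f2, models, p2, mrp)
  pulse <- pulse_params(12.9e-3, 21.8e-3, b_smm2 = 1000)
  s0j <- c(spin_echo_signal("WM", mrp, p2$timing),
           spin_echo_signal("CSF", mrp, p2$timing))
  hand <- (0.5 * s0j[1] + 0.5 * s0j[2]) *
    (0.5 * attenuation_tissue("WM", models, pulse, c(1, 0, 0), c(1, 0, 0)) +
     0.5 * attenuation_isotropic(3.19e-9, 1e9))
  expect_equal(id2[2, 3, 3, 2], hand, tolerance = 1e-12)
})

test_that("degradation preserves constants and is the identity at factor 1", {
  proto <- trim_protocol(reference_protocol(bval = 1000, factor = 2), n = 1)
  const <- array(3.7, dim = c(16, 16, 4))
  out <- degrade(const, proto)
  expect_equal(dim(out), c(8L, 8L, 2L))
  expect_equal(out, array(3.7, dim = c(8, 8, 2)), tolerance = 1e-12)
  proto1 <- trim_protocol(reference_protocol(bval = 1000, factor = 1), n = 1)
  set.seed(8)
  img <- array(stats::runif(16 * 16 * 2), dim = c(16, 16, 2))
  expect_equal(degrade(img, proto1), img, tolerance = 1e-12)
  expect_error(degrade(array(0, dim = c(15, 15, 3)),
                       trim_protocol(reference_protocol(factor = 2), 1)),
               "not divisible")
})

test_that("k-space truncation reproduces the Dirichlet-kernel Gibbs pattern", {
  # step profile constant along y: the 2D pipeline reduces to 1D truncation
  N <- 64L
  step <- ifelse(seq_len(N) > N / 4 & seq_len(N) <= 3 * N / 4, 1, 0.2)
  img <- array(rep(step, N), dim = c(N, N, 1))
  proto <- trim_protocol(reference_protocol(bval = 1000, factor = 2), n = 1)
  proto$factor <- c(2L, 1L, 1L)
  out <- degrade(img, proto)[, 1, 1]
  # oracle: naive truncated Fourier sum at the coarse sample positions
  oracle <- dirichlet_truncate(step, N / 2, pos = seq(1, N, by = 2))
  expect_equal(out, abs(oracle), tolerance = 1e-10)
  over_ours <- (max(out) - 1) / 0.8
  over_oracle <- (max(oracle) - 1) / 0.8
  expect_equal(over_ours, over_oracle, tolerance = 0.01)
  # ~9% overshoot on the fine-grid evaluation of the same series (the
  # asymptotic Wilbraham-Gibbs 8.95% plus a finite-truncation correction
  # from the second edge of the periodic profile)
  fine <- dirichlet_truncate(step, N / 2, pos = seq(1, N, by = 0.1))
  expect_gt((max(fine) - 1) / 0.8, 0.08)
  expect_lt((max(fine) - 1) / 0.8, 0.11)
})

test_that("apodization tapers the passband edge", {
  # Hamming strongly suppresses Nyquist; Fermi passes low k nearly unchanged
  w_h <- dwiphantom:::apodization_window(16, 16, "hamming")
  expect_equal(w_h[9, 9], 1, tolerance = 1e-12)        # DC untouched
  expect_lt(w_h[1, 9], 0.1)
  w_f <- dwiphantom:::apodization_window(16, 16, "fermi")
  expect_gt(w_f[9, 9], 0.999)
  expect_lt(w_f[1, 9], 0.5)
  # filtered degradation of a constant still preserves it (DC gain 1)
  proto <- trim_protocol(reference_protocol(bval = 1000, factor = 2), n = 1)
  proto$filter <- "hamming"
  const <- array(1, dim = c(16, 16, 2))
  expect_equal(degrade(const, proto),
               array(1, dim = c(8, 8, 1)), tolerance = 1e-12)
})

test_that("k-space crop never increases the image L2 norm", {
  set.seed(5)
  proto <- trim_protocol(reference_protocol(bval = 1000, factor = 2), n = 1)
  for (rep in 1:3) {
    img <- array(stats::runif(16 * 16 * 2), dim = c(16, 16, 2))
    out <- degrade(img, proto)
    # Parseval: mean square per voxel cannot grow under central cropping
    expect_lte(sum(out^2) * 4, sum(img^2) + 1e-9)
  }
})

test_that("k-space noise is calibrated and Rayleigh in the background", {
  proto <- reference_protocol(bval = 1000, factor = 1, snr = 20, seed = 3)
  sigma_img <- 0.05
  sigma_k <- kspace_sigma(1, 1 / sigma_img, c(64, 64), c(1, 1, 1))
  zero <- array(0, dim = c(64, 64, 3))
  out <- degrade(zero, trim_protocol(proto, 1), sigma_k = sigma_k, seed = 21)
  ks <- stats::ks.test(as.vector(out),
                       function(q) 1 - exp(-q^2 / (2 * sigma_img^2)))
  expect_gt(ks$p.value, 0.01)
  # bright uniform region at SNR 20: Rician moments within 3 SE
  bright <- array(1, dim = c(64, 64, 3))
  nu <- 1; sigma <- nu / 20
  sk <- kspace_sigma(nu, 20, c(64, 64), c(1, 1, 1))
  outb <- degrade(bright, trim_protocol(proto, 1), sigma_k = sk, seed = 22)
  n <- length(outb)
  expect_lt(abs(mean(outb) - rician_mean(nu, sigma)),
            3 * rician_sd(nu, sigma) / sqrt(n))
  expect_lt(abs(stats::sd(outb) - rician_sd(nu, sigma)),
            3 * rician_sd(nu, sigma) / sqrt(n))    # conservative SE bound
  # SNR = Inf leaves k-space untouched
  k <- array(complex(real = 1:8, imaginary = 8:1), dim = c(2, 2, 2))
  expect_identical(add_kspace_noise(k, Inf, 1), k)
})

test_that("full acquisitions are shaped, bounded and deterministic", {
  sb <- small_substrate()
  proto <- trim_protocol(reference_protocol(bval = 1000, factor = 2,
                                            snr = 25, seed = 13), n = 4)
  acq <- simulate_acquisition(sb$vf, sb$tractogram, proto = proto)
  expect_equal(dim(acq$data), c(16, 16, 16, 5))
  expect_true(all(acq$data >= 0))
  acq2 <- simulate_acquisition(sb$vf, sb$tractogram, proto = proto)
  expect_identical(acq$data, acq2$data)
  # noiseless factor-1 run equals the ideal volumes to round-off
  proto0 <- trim_protocol(reference_protocol(bval = 1000, factor = 1,
                                             seed = 13), n = 2)
  field <- assign_segments(sb$tractogram, sb$vf)
  ideal <- ideal_dw_volumes(sb$vf, field, tissue_models(), proto0)
  acq0 <- simulate_acquisition(sb$vf, sb$tractogram, proto = proto0)
  expect_lt(max(abs(acq0$data - ideal)), 1e-10)
  # provenance carries the seeds
  expect_equal(acq$provenance$seed, 13L)
  expect_length(acq$provenance$volume_seeds, 5)
})

test_that("acquisitions are written as NIfTI + bval/bvec + provenance", {
  sb <- small_substrate()
  proto <- trim_protocol(reference_protocol(bval = 1000, factor = 2,
                                            seed = 4), n = 3)
  acq <- simulate_acquisition(sb$vf, sb$tractogram, proto = proto)
  prefix <- file.path(withr::local_tempdir(), "acq")
  paths <- write_acquisition(acq, prefix)
  expect_true(all(file.exists(paths)))
  nii <- read_nifti(paths["nii"])
  expect_equal(dim(nii$img), dim(acq$data))
  expect_equal(nii$affine, acq$affine, tolerance = 1e-6)
  bv <- scan(paths["bval"], quiet = TRUE)
  expect_equal(bv, acq$scheme$b_smm2)
  bvec <- matrix(scan(paths["bvec"], quiet = TRUE), nrow = 3, byrow = TRUE)
  expect_equal(bvec[1, ], acq$scheme$gx, tolerance = 1e-12)
})
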