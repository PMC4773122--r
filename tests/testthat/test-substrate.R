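test_that("generated fraction maps satisfy their invariants", {
  sb <- small_substrate()
  vf <- sb$vf
  fr <- vf$fractions
  expect_true(all(fr >= 0 & fr <= 1))
  sums <- apply(fr, 1:3, sum)
  expect_lt(max(abs(sums[vf$brain_mask] - 1)), 1e-6)
  expect_equal(max(sums[!vf$brain_mask]), 0)
  # all four tissues are present
  expect_true(all(apply(fr, 4, sum) > 0))
  # affine consistent with stated voxel size
  expect_equal(vf$voxel_size_mm, rep(0.7, 3), tolerance = 1e-12)
})

test_that("generation is deterministic for a fixed seed", {
  rec <- small_recipe(seed = 11L, grid = 24L)
  a <- suppressWarnings(generate_numerical_brain(rec))
  b <- suppressWarnings(generate_numerical_brain(rec))
  expect_identical(a, b)
  c <- suppressWarnings(generate_numerical_brain(small_recipe(seed = 12L,
                                                              grid = 24L)))
  expect_false(identical(a$tractogram, c$tractogram))
})

test_that("a single straight x bundle yields segment directions (1,0,0)", {
  sb <- generate_numerical_brain(straight_recipe())
  dirs <- do.call(rbind, lapply(sb$tractogram$streamlines, function(s)
    s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE]))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  expect_lt(max(abs(abs(dirs[, 1]) - 1)), 1e-9)
  expect_lt(max(abs(dirs[, 2:3])), 1e-9)
})

test_that("90-degree crossing produces two antipodal direction clusters", {
  rec <- substrate_recipe(grid_shape = c(32L, 32L, 32L), rng_seed = 5L,
                          bundles = list(list(type = "crossing",
                                              angle_deg = 90,
                                              radius_mm = 2.5,
                                              n_streamlines = 60)),
                          csf_cavity = NULL, dgm_blobs = list())
  sb <- generate_numerical_brain(rec)
  field <- assign_segments(sb$tractogram, sb$vf)
  # overlap voxels: near the grid center where both tubes pass
  multi <- which(field$counts >= 4, arr.ind = TRUE)
  ctr <- (sb$vf$grid_shape - 1) / 2
  near <- multi[rowSums(sweep(multi - 1, 2, ctr)^2) < 2^2, , drop = FALSE]
  expect_gt(nrow(near), 0)
  found <- 0L
  for (i in seq_len(nrow(near))) {
    lin <- (near[i, 1] - 1) + 32 * ((near[i, 2] - 1) + 32 * (near[i, 3] - 1)) + 1
    d <- field$directions[[as.character(lin)]]
    # cluster by sign-invariant similarity to the first direction
    sim <- abs(d %*% d[1, ])
    g1 <- sim > 0.9; g2 <- sim < 0.5
    if (sum(g1) && sum(g2)) {
      m1 <- colMeans(d[g1, , drop = FALSE] * sign(d[g1, 1]))
      m2 <- colMeans(d[g2, , drop = FALSE] * sign(d[g2, 1]))
      ang <- acos(min(1, abs(sum(m1 * m2) / sqrt(sum(m1^2) * sum(m2^2)))))
      expect_lt(abs(ang * 180 / pi - 90), 5)
      found <- found + 1L
    }
  }
  expect_gt(found, 0)
})

test_that("streamlines stay in WM-dominant voxels; bundle core is covered", {
  sb <- small_substrate()
  vf <- sb$vf
  pts <- do.call(rbind, lapply(sb$tractogram$streamlines, function(s)
    s[-c(1, nrow(s)), , drop = FALSE]))
  idx <- round(dwiphantom:::world_to_voxel(pts, vf$affine)) + 1
  wm <- vf$fractions[, , , "WM"][cbind(idx[, 1], idx[, 2], idx[, 3])]
  expect_true(all(wm >= 0.5))
  # bundle-core voxels (centers within the streamline fill radius of either
  # crossing centerline) all carry at least one segment
  field <- assign_segments(sb$tractogram, vf)
  gs <- vf$grid_shape; vs <- vf$voxel_size_mm
  ctr <- (gs - 1) / 2 * vs
  vox <- as.matrix(expand.grid(x = seq_len(gs[1]) - 1,
                               y = seq_len(gs[2]) - 1,
                               z = seq_len(gs[3]) - 1))
  w <- sweep(vox, 2, vs, `*`)
  half <- 30 * pi / 180
  core <- rep(FALSE, nrow(w))
  for (u in list(c(cos(half), sin(half), 0), c(cos(half), -sin(half), 0))) {
    dd <- sweep(w, 2, ctr)
    pr <- dd %*% u
    dist <- sqrt(pmax(0, rowSums(dd^2) - pr[, 1]^2))
    core <- core | (dist <= 0.7 * 2.5 - 0.3 & abs(pr[, 1]) < 7)
  }
  expect_true(all(field$counts[array(core, gs)] > 0))
})

test_that("recipe validation rejects bad geometry", {
  expect_error(substrate_recipe(bundles = list()), "at least one bundle")
  expect_error(substrate_recipe(bundles = list(list(type = "crossing",
                                                    angle_deg = 120,
                                                    radius_mm = 2))),
               "\\(0, 90\\]")
  expect_error(substrate_recipe(bundles = list(list(type = "wiggly",
                                                    radius_mm = 2))),
               "unknown bundle type")
  # oversized cavity exceeds the grid
  rec <- substrate_recipe(grid_shape = c(16L, 16L, 16L),
                          csf_cavity = list(center_frac = c(0.5, 0.5, 0.5),
                                            radii_mm = c(20, 20, 20)),
                          dgm_blobs = list())
  expect_error(generate_numerical_brain(rec), "exceeds the grid")
})

test_that("fraction maps round-trip through NIfTI", {
  sb <- small_substrate()
  path <- withr::local_tempfile(fileext = ".nii")
  write_fraction_map(sb$vf, path)
  back <- read_fraction_map(path)
  # affine preserved to its float32 storage precision (NIfTI-1 srow fields)
  expect_equal(back$affine, sb$vf$affine, tolerance = 1e-6)
  expect_equal(back$fractions, sb$vf$fractions, tolerance = 1e-6)
  expect_equal(back$brain_mask, sb$vf$brain_mask)
  # four scalar component files are accepted too
  dir4 <- withr::local_tempdir()
  paths <- file.path(dir4, paste0(c("wm", "cgm", "dgm", "csf"), ".nii"))
  for (j in 1:4)
    write_nifti(array(sb$vf$fractions[, , , j], dim = sb$vf$grid_shape),
                paths[j], affine = sb$vf$affine)
  back4 <- read_fraction_map(paths)
  expect_equal(back4$fractions, sb$vf$fractions, tolerance = 1e-6)
})

test_that("invalid fraction files are rejected with diagnostics", {
  sb <- small_substrate()
  # negative fraction
  bad <- sb$vf$fractions
  bad[5, 5, 5, 1] <- -0.2
  path <- withr::local_tempfile(fileext = ".nii")
  write_nifti(bad, path, affine = sb$vf$affine)
  expect_error(read_fraction_map(path), "outside \\[0, 1\\] at 1 voxel")
  # 3-component file names the missing class
  path3 <- withr::local_tempfile(fileext = ".nii")
  write_nifti(sb$vf$fractions[, , , 1:3], path3, affine = sb$vf$affine)
  expect_error(read_fraction_map(path3), "4 classes WM, CGM, DGM, CSF")
})

test_that("tractograms round-trip through TCK exactly at float32", {
  sb <- small_substrate()
  tr <- tractogram(sb$tractogram$streamlines[1:10], nominal_step_mm = 0.7)
  path <- withr::local_tempfile(fileext = ".tck")
  write_tractogram(tr, path)
  back <- read_tractogram(path)
  expect_length(back$streamlines, 10)
  expect_equal(back$nominal_step_mm, 0.7)
  for (i in 1:10)
    expect_equal(back$streamlines[[i]],
                 matrix(as.double(
                   writeBin(as.double(t(tr$streamlines[[i]])), raw(),
                            size = 4L) |> readBin("double", 3e3, size = 4L)),
                   ncol = 3, byrow = TRUE),
                 tolerance = 0)
})

test_that("degenerate TCK content is handled explicitly", {
  # single-point streamline dropped with a message
  sl <- list(cbind(c(0, 1), c(0, 0), c(0, 0)), matrix(c(5, 5, 5), 1))
  tr <- tractogram(sl, nominal_step_mm = 1, validate = FALSE)
  path <- withr::local_tempfile(fileext = ".tck")
  write_tractogram(tr, path)
  expect_message(back <- read_tractogram(path), "1 streamline")
  expect_length(back$streamlines, 1)
  # empty tractogram warns
  path2 <- withr::local_tempfile(fileext = ".tck")
  write_tractogram(tractogram(list(), validate = FALSE), path2)
  expect_warning(empty <- read_tractogram(path2), "empty tractogram")
  expect_length(empty$streamlines, 0)
  # malformed header errors
  path3 <- withr::local_tempfile(fileext = ".tck")
  writeLines("not a tractogram", path3)
  expect_error(read_tractogram(path3), "bad magic")
})

test_that("tractogram constructor enforces its invariants", {
  expect_error(tractogram(list(matrix(c(0, 0, 0), 1))), ">= 2 points")
  dup <- list(rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(tractogram(dup), "distinct")
  # mean step more than 20% off nominal
  far <- list(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_error(tractogram(far, nominal_step_mm = 0.7), "deviates")
})
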