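# Synthetic brain-like substrate: tissue volume-fraction maps and streamline
# tractograms with the geometric configurations (crossing / bending / kissing
# bundles, GM rim, CSF cavity, deep-GM blobs) that make tractography hard.

TISSUES <- c("WM", "CGM", "DGM", "CSF")

#' Tissue volume-fraction map
#'
#' Per-voxel volume fractions of the four modeled tissue classes (white
#' matter, cortical grey matter, deep grey matter, CSF) on a regular grid.
#' Fractions sum to 1 inside the brain mask and to 0 outside.
#'
#' @param fractions 4D array `[nx, ny, nz, 4]`; 4th dimension ordered/named
#'   `WM, CGM, DGM, CSF`.
#' @param affine 4x4 voxel-index (0-based, voxel centers) to world-mm
#'   transform.
#' @param brain_mask logical 3D array; derived from the fraction sum if
#'   omitted.
#' @param validate check invariants (sum-to-one, range).
#' @return object of class `tissue_fraction_map`.
#' @export
tissue_fraction_map <- function(fractions, affine = diag(4),
                                brain_mask = NULL, validate = TRUE) {
  stopifnot(length(dim(fractions)) == 4)
  if (dim(fractions)[4] != 4) {
    have <- dimnames(fractions)[[4]] %||% as.character(seq_len(dim(fractions)[4]))
    stop("fraction map must carry 4 tissue classes (WM, CGM, DGM, CSF); ",
         "got ", dim(fractions)[4], " (", paste(have, collapse = ", "),
         "); missing: ", paste(setdiff(TISSUES, have), collapse = ", "))
  }
  dimnames(fractions) <- c(rep(list(NULL), 3), list(TISSUES))
  sums <- rowSums(matrix(fractions, ncol = 4))
  dim(sums) <- dim(fractions)[1:3]
  if (is.null(brain_mask)) brain_mask <- sums > 0.5
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  obj <- structure(list(fractions = fractions, affine = affine,
                        voxel_size_mm = voxel_size, brain_mask = brain_mask,
                        grid_shape = dim(fractions)[1:3]),
                   class = "tissue_fraction_map")
  if (validate) {
    rng_bad <- sum(fractions < -1e-6 | fractions > 1 + 1e-6)
    if (rng_bad > 0)
      stop("fractions outside [0, 1] at ", rng_bad, " voxel entries")
    if (any(abs(sums[brain_mask] - 1) > 1e-4))
      stop("fractions do not sum to 1 inside the brain mask (max dev ",
           signif(max(abs(sums[brain_mask] - 1)), 3), ")")
    if (any(sums[!brain_mask] > 1e-4))
      stop("non-zero fractions outside the brain mask")
  }
  obj
}

#' @export
print.tissue_fraction_map <- function(x, ...) {
  cat("<tissue_fraction_map> grid", paste(x$grid_shape, collapse = "x"),
      "voxel", paste(signif(x$voxel_size_mm, 3), collapse = "x"), "mm,",
      sum(x$brain_mask), "brain voxels\n")
  invisible(x)
}

#' Streamline tractogram in world millimeters
#'
#' @param streamlines list of n x 3 point matrices (world mm).
#' @param nominal_step_mm nominal inter-point distance (default 0.7 mm, the
#'   sub-voxel step of the native 0.7 mm protocols).
#' @param validate check invariants (>= 2 points, distinct consecutive
#'   points, mean step within 20% of nominal).
#' @return object of class `tractogram`.
#' @export
tractogram <- function(streamlines, nominal_step_mm = 0.7, validate = TRUE) {
  stopifnot(is.list(streamlines))
  if (validate && length(streamlines)) {
    npts <- vapply(streamlines, nrow, 0L)
    if (any(npts < 2L)) stop("streamlines must have >= 2 points")
    steps <- unlist(lapply(streamlines, function(s) {
      d <- s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE]
      sqrt(rowSums(d^2))
    }))
    if (any(steps == 0)) stop("consecutive streamline points must be distinct")
    if (is.finite(nominal_step_mm) &&
        abs(mean(steps) - nominal_step_mm) > 0.2 * nominal_step_mm)
      stop(sprintf("mean step %.3f mm deviates > 20%% from nominal %.3f mm",
                   mean(steps), nominal_step_mm))
  }
  structure(list(streamlines = streamlines,
                 nominal_step_mm = nominal_step_mm),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  n <- length(x$streamlines)
  cat("<tractogram>", n, "streamlines, nominal step",
      x$nominal_step_mm, "mm\n")
  invisible(x)
}

n_segments <- function(tractogram) {
  sum(vapply(tractogram$streamlines, nrow, 0L) - 1L)
}

#' Recipe for a synthetic numerical brain
#'
#' Describes the geometry of a brain-like substrate: an ellipsoidal brain
#' with a cortical-GM rim, a CSF cavity, deep-GM blobs and parameterized
#' white-matter bundles.
#'
#' @param grid_shape integer triple.
#' @param voxel_size_mm positive real triple (scalar recycled).
#' @param rng_seed integer seed controlling all randomness.
#' @param bundles list of bundle specs; each a list with `type` in
#'   `"straight"`, `"crossing"`, `"arc"`, `"kissing"` plus `radius_mm`,
#'   `n_streamlines` and type-specific fields (`axis` for straight,
#'   `angle_deg` for crossing, `span_deg`/`curvature_mm` for arc/kissing).
#' @param gm_rim_mm cortical rim thickness (mm).
#' @param csf_cavity `NULL` or list(`center_frac`, `radii_mm`).
#' @param dgm_blobs list of list(`center_frac`, `radius_mm`).
#' @param step_mm streamline step size (mm).
#' @return object of class `substrate_recipe`.
#' @export
substrate_recipe <- function(grid_shape = c(48L, 48L, 48L),
                             voxel_size_mm = 0.7,
                             rng_seed = 1L,
                             bundles = list(list(type = "crossing",
                                                 angle_deg = 60,
                                                 radius_mm = 2.5,
                                                 n_streamlines = 90)),
                             gm_rim_mm = 1.5,
                             csf_cavity = list(center_frac = c(0.5, 0.5, 0.70),
                                               radii_mm = c(4, 3, 3)),
                             dgm_blobs = list(
                               list(center_frac = c(0.32, 0.5, 0.30),
                                    radius_mm = 2.8),
                               list(center_frac = c(0.68, 0.5, 0.30),
                                    radius_mm = 2.8)),
                             step_mm = 0.7) {
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  if (!length(bundles)) stop("recipe must contain at least one bundle")
  for (b in bundles) {
    if (is.null(b$type) ||
        !b$type %in% c("straight", "crossing", "arc", "kissing"))
      stop("unknown bundle type: ", b$type %||% "<missing>")
    if (identical(b$type, "crossing")) {
      ang <- b$angle_deg %||% stop("crossing bundle needs angle_deg")
      if (ang <= 0 || ang > 90)
        stop("crossing angle must be in (0, 90] degrees; got ", ang)
    }
    if ((b$radius_mm %||% 0) <= 0) stop("bundle radius_mm must be > 0")
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 rng_seed = as.integer(rng_seed), bundles = bundles,
                 gm_rim_mm = gm_rim_mm, csf_cavity = csf_cavity,
                 dgm_blobs = dgm_blobs, step_mm = step_mm),
            class = "substrate_recipe")
}

# --- internal geometry -------------------------------------------------------

recipe_frame <- function(recipe) {
  vs <- recipe$voxel_size_mm
  affine <- diag(c(vs, 1))
  extent <- recipe$grid_shape * vs
  center <- (recipe$grid_shape - 1) / 2 * vs
  semi <- 0.45 * extent / 2 * 2       # ellipsoid semi-axes: 45% of extent
  list(affine = affine, extent = extent, center = center, semi = semi)
}

# normalized ellipsoid radius; <= 1 is inside the brain
ellipsoid_rho <- function(pts, center, semi) {
  sqrt(((pts[, 1] - center[1]) / semi[1])^2 +
       ((pts[, 2] - center[2]) / semi[2])^2 +
       ((pts[, 3] - center[3]) / semi[3])^2)
}

# largest t with rho(center + t*u) <= target (bisection; u unit)
ray_extent <- function(u, frame, target) {
  f <- function(t) ellipsoid_rho(matrix(frame$center + t * u, 1), frame$center,
                                 frame$semi) - target
  hi <- max(frame$semi) * 1.5
  stats::uniroot(f, c(0, hi))$root
}

# Expand user bundle specs into tube definitions, each with a densely sampled
# centerline polyline (world mm).
expand_bundles <- function(recipe, frame) {
  rim_norm <- recipe$gm_rim_mm / min(frame$semi)
  inner <- 1 - rim_norm                   # centerlines end at the rim
  tubes <- list()
  sample_line <- function(a, b, ds = 0.25) {
    L <- vnorm(b - a)
    t <- seq(0, 1, length.out = max(2L, ceiling(L / ds) + 1L))
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
          a[3] + t * (b[3] - a[3]))
  }
  straight_tube <- function(u, radius, n_sl, frac = 1) {
    u <- u / vnorm(u)
    t_max <- ray_extent(u, frame, inner) * frac
    t_min <- -ray_extent(-u, frame, inner) * frac
    a <- frame$center + t_min * u
    b <- frame$center + t_max * u
    list(centerline = sample_line(a, b), radius = radius, n_sl = n_sl)
  }
  arc_tube <- function(radius, n_sl, curvature, span_deg, flip = 1,
                       offset = c(0, 0, 0)) {
    # circular arc in the xy-plane through the brain center
    cc <- frame$center + offset + c(0, -flip * curvature, 0)
    ang <- span_deg * pi / 180
    th <- seq(pi / 2 - ang / 2, pi / 2 + ang / 2,
              length.out = max(8L, ceiling(curvature * ang / 0.25)))
    pts <- cbind(cc[1] + curvature * cos(th),
                 cc[2] + flip * curvature * sin(th),
                 rep(cc[3], length(th)))
    list(centerline = pts, radius = radius, n_sl = n_sl)
  }
  for (b in recipe$bundles) {
    n_sl <- b$n_streamlines %||% 80L
    r <- b$radius_mm
    tubes <- c(tubes, switch(
      b$type,
      straight = list(straight_tube(b$axis %||% c(1, 0, 0), r, n_sl,
                                    b$length_frac %||% 1)),
      crossing = {
        half <- (b$angle_deg / 2) * pi / 180
        list(straight_tube(c(cos(half), sin(half), 0), r, n_sl),
             straight_tube(c(cos(half), -sin(half), 0), r, n_sl))
      },
      arc = list(arc_tube(r, n_sl, b$curvature_mm %||% (min(frame$semi) * 0.55),
                          b$span_deg %||% 120,
                          offset = b$offset_mm %||% c(0, 0, 0))),
      kissing = {
        curv <- b$curvature_mm %||% (min(frame$semi) * 0.5)
        span <- b$span_deg %||% 100
        # two arcs curving away from each other, tangent near the center
        list(arc_tube(r, n_sl, curv, span, flip = 1,
                      offset = c(0, r * 1.05, 0)),
             arc_tube(r, n_sl, curv, span, flip = -1,
                      offset = c(0, -r * 1.05, 0)))
      }))
  }
  tubes
}

validate_geometry <- function(recipe, frame, tubes) {
  lo <- -recipe$voxel_size_mm / 2
  hi <- (recipe$grid_shape - 0.5) * recipe$voxel_size_mm
  for (tb in tubes) {
    cl <- tb$centerline
    mins <- apply(cl, 2, min) - tb$radius
    maxs <- apply(cl, 2, max) + tb$radius
    if (any(mins < lo) || any(maxs > hi))
      stop("bundle geometry exceeds the grid bounds")
  }
  if (!is.null(recipe$csf_cavity)) {
    c0 <- recipe$csf_cavity$center_frac * frame$extent
    if (any(c0 - recipe$csf_cavity$radii_mm < lo) ||
        any(c0 + recipe$csf_cavity$radii_mm > hi))
      stop("CSF cavity exceeds the grid bounds")
  }
  for (bl in recipe$dgm_blobs %||% list()) {
    c0 <- bl$center_frac * frame$extent
    if (any(c0 - bl$radius_mm < lo) || any(c0 + bl$radius_mm > hi))
      stop("DGM blob exceeds the grid bounds")
    for (tb in tubes) {
      if (min(min_dist_to_polyline(matrix(c0, 1), tb$centerline)) <
          bl$radius_mm + tb$radius)
        warning("DGM blob overlaps a bundle tube; the tube takes priority ",
                "and the blob is locally truncated", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# chunked min distance from many points to a sampled polyline
min_dist_to_polyline <- function(pts, poly, chunk = 20000L) {
  out <- numeric(nrow(pts))
  for (start in seq(1L, nrow(pts), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(pts))
    p <- pts[idx, , drop = FALSE]
    d2 <- outer(rowSums(p^2), rep(1, nrow(poly))) +
      outer(rep(1, nrow(p)), rowSums(poly^2)) - 2 * p %*% t(poly)
    out[idx] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

# streamlines filling a tube: sunflower-layout perpendicular offsets with a
# small seeded jitter, points spaced at the nominal step along the centerline
tube_streamlines <- function(tube, step_mm) {
  cl <- tube$centerline
  seg <- diff(cl)
  arc <- c(0, cumsum(sqrt(rowSums(seg^2))))
  L <- arc[length(arc)]
  # keep one step of margin at the tube end caps so only terminal points sit
  # in boundary partial-volume voxels
  s <- seq(step_mm, L - step_mm, by = step_mm)
  if (length(s) < 2) s <- c(0, L)
  # interpolate centerline and a parallel-transported-ish frame
  interp <- function(v) stats::approx(arc, v, xout = s)$y
  base <- cbind(interp(cl[, 1]), interp(cl[, 2]), interp(cl[, 3]))
  tang <- rbind(base[2, ] - base[1, ], diff(base))
  tang <- tang / sqrt(rowSums(tang^2))
  # frame vectors perpendicular to the local tangent
  up <- c(0, 0, 1)
  e1 <- cbind(tang[, 2] * up[3] - tang[, 3] * up[2],
              tang[, 3] * up[1] - tang[, 1] * up[3],
              tang[, 1] * up[2] - tang[, 2] * up[1])
  n1 <- sqrt(rowSums(e1^2))
  bad <- n1 < 1e-6                          # tangent ~ parallel to z
  if (any(bad)) { e1[bad, 1] <- 1; e1[bad, 2] <- 0; e1[bad, 3] <- 0
                  n1[bad] <- 1 }
  e1 <- e1 / n1
  e2 <- cbind(tang[, 2] * e1[, 3] - tang[, 3] * e1[, 2],
              tang[, 3] * e1[, 1] - tang[, 1] * e1[, 3],
              tang[, 1] * e1[, 2] - tang[, 2] * e1[, 1])
  n <- tube$n_sl
  i <- seq_len(n)
  # fill the inner 70% of the tube cross-section: max offset + voxel
  # half-diagonal stays below the tube radius, so every non-terminal point
  # lands in a WM-dominant voxel; the outer shell is partial-volume
  # territory handled by the powder-average fallback
  rr <- tube$radius * 0.70 * sqrt((i - 0.5) / n)
  th <- 2 * pi * (1 + sqrt(5)) / 2 * i
  offs <- cbind(rr * cos(th), rr * sin(th)) +
    matrix(stats::rnorm(2 * n, sd = 0.03), ncol = 2)
  lapply(i, function(k) {
    base + offs[k, 1] * e1 + offs[k, 2] * e2
  })
}

#' Generate a synthetic numerical brain
#'
#' Rasterizes the recipe's geometry into a tissue volume-fraction map
#' (fraction = occupancy on a 3x3x3 sub-voxel grid, which anti-aliases the
#' tissue interfaces into partial-volume fractions) and fills each
#' white-matter bundle with streamlines at the nominal step size.
#' Deterministic for a fixed `rng_seed`.
#'
#' @param recipe a [substrate_recipe].
#' @return list with `vf` (a [tissue_fraction_map]) and `tractogram`
#'   (a [tractogram]).
#' @export
generate_numerical_brain <- function(recipe) {
  stopifnot(inherits(recipe, "substrate_recipe"))
  frame <- recipe_frame(recipe)
  tubes <- expand_bundles(recipe, frame)
  validate_geometry(recipe, frame, tubes)
  gs <- recipe$grid_shape
  vs <- recipe$voxel_size_mm

  # 3x3x3 sub-voxel sample offsets (voxel units)
  off1 <- c(-1, 0, 1) / 3
  sub <- as.matrix(expand.grid(x = off1, y = off1, z = off1))

  vox <- as.matrix(expand.grid(x = seq_len(gs[1]) - 1L,
                               y = seq_len(gs[2]) - 1L,
                               z = seq_len(gs[3]) - 1L))
  nvox <- nrow(vox)
  counts <- matrix(0L, nvox, 4, dimnames = list(NULL, TISSUES))
  inside_any <- integer(nvox)

  rim_norm <- recipe$gm_rim_mm / min(frame$semi)
  cav <- recipe$csf_cavity
  cav_c <- if (!is.null(cav)) cav$center_frac * frame$extent
  blobs <- recipe$dgm_blobs %||% list()

  for (k in seq_len(nrow(sub))) {
    pts <- sweep(vox, 2, sub[k, ], `+`)
    pts <- sweep(pts, 2, vs, `*`)           # world mm (affine is diagonal)
    rho <- ellipsoid_rho(pts, frame$center, frame$semi)
    cls <- integer(nvox)                    # 0 = background
    in_brain <- rho <= 1
    # WM tubes claim first: bundles are never carved by cavity or blobs,
    # which keeps every streamline inside WM territory
    if (any(in_brain)) {
      is_wm <- rep(FALSE, nvox)
      for (tb in tubes) {
        dt <- rep(Inf, nvox)
        dt[in_brain] <- min_dist_to_polyline(pts[in_brain, , drop = FALSE],
                                             tb$centerline)
        is_wm <- is_wm | (in_brain & dt <= tb$radius)
      }
      cls[is_wm] <- 1L
    }
    # CSF cavity
    if (!is.null(cav)) {
      d <- sqrt(((pts[, 1] - cav_c[1]) / cav$radii_mm[1])^2 +
                ((pts[, 2] - cav_c[2]) / cav$radii_mm[2])^2 +
                ((pts[, 3] - cav_c[3]) / cav$radii_mm[3])^2)
      cls[in_brain & cls == 0L & d <= 1] <- 4L
    }
    for (bl in blobs) {
      c0 <- bl$center_frac * frame$extent
      d <- sqrt((pts[, 1] - c0[1])^2 + (pts[, 2] - c0[2])^2 +
                (pts[, 3] - c0[3])^2)
      cls[in_brain & cls == 0L & d <= bl$radius_mm] <- 3L
    }
    # cortical rim, then default interior = CGM
    cls[in_brain & cls == 0L & rho > 1 - rim_norm] <- 2L
    cls[in_brain & cls == 0L] <- 2L
    for (j in 1:4) counts[, j] <- counts[, j] + (cls == j)
    inside_any <- inside_any + (cls > 0L)
  }
  fr <- counts / nrow(sub)
  # renormalize brain-boundary voxels: fractions are conditional on brain
  # occupancy >= half the sub-samples (sharp outer edge, per-voxel sum == 1)
  occ <- inside_any / nrow(sub)
  mask <- occ >= 0.5
  fr[mask, ] <- fr[mask, ] / rowSums(fr[mask, , drop = FALSE])
  fr[!mask, ] <- 0
  fractions <- array(fr, dim = c(gs, 4L),
                     dimnames = c(rep(list(NULL), 3), list(TISSUES)))
  brain_mask <- array(mask, dim = gs)
  vf <- tissue_fraction_map(fractions, frame$affine, brain_mask)

  sl <- with_seed(recipe$rng_seed, {
    unlist(lapply(tubes, tube_streamlines, step_mm = recipe$step_mm),
           recursive = FALSE)
  })
  list(vf = vf, tractogram = tractogram(sl, nominal_step_mm = recipe$step_mm))
}

# --- fraction-map file I/O ---------------------------------------------------

#' Write / read a tissue fraction map as 4D NIfTI
#'
#' One 4D file whose 4th dimension holds the WM, CGM, DGM, CSF fractions in
#' that order.  The affine is honored exactly; fractions are stored float32.
#'
#' @param map a [tissue_fraction_map].
#' @param path a `.nii` path.
#' @return `write_fraction_map`: `path` invisibly; `read_fraction_map`: a
#'   [tissue_fraction_map].
#' @export
write_fraction_map <- function(map, path) {
  stopifnot(inherits(map, "tissue_fraction_map"))
  write_nifti(map$fractions, path, affine = map$affine)
}

#' @rdname write_fraction_map
#' @param path one 4D `.nii` file, or a character vector of 4 scalar 3D
#'   files in WM, CGM, DGM, CSF order (read form only).
#' @export
read_fraction_map <- function(path) {
  if (length(path) == 4) {                # four scalar component files
    parts <- lapply(path, read_nifti)
    dims <- lapply(parts, function(p) dim(p$img))
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
      stop("the 4 component files disagree on grid shape")
    for (p in parts[-1])
      if (max(abs(p$affine - parts[[1]]$affine)) > 1e-5)
        stop("the 4 component files disagree on the affine")
    img <- array(unlist(lapply(parts, `[[`, "img")),
                 dim = c(dims[[1]], 4L))
    nii <- list(img = img, affine = parts[[1]]$affine)
  } else {
    nii <- read_nifti(path)
  }
  if (length(dim(nii$img)) != 4)
    stop("fraction map must be a 4D volume (4 tissue components)")
  if (dim(nii$img)[4] != 4)
    stop("fraction map has ", dim(nii$img)[4],
         " components; expected the 4 classes WM, CGM, DGM, CSF")
  bad <- sum(nii$img < -1e-4 | nii$img > 1 + 1e-4)
  if (bad > 0)
    stop("fractions outside [0, 1] at ", bad, " voxel entries in ", path)
  img <- pmin(pmax(nii$img, 0), 1)
  dim(img) <- dim(nii$img)
  tissue_fraction_map(img, affine = nii$affine)
}
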