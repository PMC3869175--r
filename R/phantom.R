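# Synthetic phantoms with analytic ground truth. The inside test is purely
# analytic (truncated-ellipsoid shells, optionally deformed and rigidly
# posed); no mesh rasterization is involved, so phantoms are an independent
# oracle for every pipeline stage. Deformations are restricted to analytic,
# invertible maps so the true displacement is known exactly at any point.

#' Phantom specification
#'
#' Defaults describe a normal adult human left ventricle at end diastole:
#' outer semi-axes (33, 33, 52) mm, 10 mm wall, base plane 35% of the long
#' semi-axis above the equator; the BiV variant adds a thinner RV shell
#' (4 mm wall) as an ellipsoid offset laterally so its free wall forms a
#' crescent on the LV epicardium.
#'
#' @param topology `"LV"` or `"BiV"`.
#' @param lv_outer_radii LV outer semi-axes (mm).
#' @param wall_thickness LV wall thickness (mm).
#' @param base_height basal truncation plane height above the centre (mm).
#' @param rv_size RV outer ellipsoid semi-axes (mm).
#' @param rv_center_offset RV ellipsoid centre offset along +x (mm);
#'   default `0.72 * lv_outer_radii[1]`.
#' @param rv_wall_thickness RV wall thickness (mm).
#' @param spacing voxel spacing (mm).
#' @param margin_mm empty border around the anatomy (mm).
#' @param deformation `NULL`, or `list(type = "affine", A = 3x3, b = 3)`, or
#'   `list(type = "bump", amplitude, wavelength, axis, along)` (sinusoidal
#'   in-plane displacement along `axis` driven by coordinate `along`).
#' @param pose `NULL` or `list(R = 3x3 rotation, t = translation mm)`
#'   applied after the deformation.
#' @param interslice_distance optional mm, applied via [sparsify()].
#' @param slice_shifts optional per-slice in-plane shifts (mm), applied via
#'   [apply_slice_shift()].
#' @param seed integer recorded with the spec (generation is deterministic).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(topology = c("LV", "BiV"),
                         lv_outer_radii = c(33, 33, 52),
                         wall_thickness = 10,
                         base_height = 0.35 * lv_outer_radii[3],
                         rv_size = c(24, 27, 36),
                         rv_center_offset = 0.72 * lv_outer_radii[1],
                         rv_wall_thickness = 4,
                         spacing = c(1, 1, 1),
                         margin_mm = 8,
                         deformation = NULL,
                         pose = NULL,
                         interslice_distance = NULL,
                         slice_shifts = NULL,
                         seed = 1L) {
  topology <- match.arg(topology)
  if (wall_thickness <= 0 || wall_thickness >= min(lv_outer_radii))
    stop("invalid wall thickness")
  structure(list(
    topology = topology, lv_outer_radii = as.numeric(lv_outer_radii),
    wall_thickness = wall_thickness, base_height = base_height,
    rv_size = as.numeric(rv_size), rv_center_offset = rv_center_offset,
    rv_wall_thickness = rv_wall_thickness,
    spacing = rep(as.numeric(spacing), length.out = 3),
    margin_mm = margin_mm, deformation = deformation, pose = pose,
    interslice_distance = interslice_distance, slice_shifts = slice_shifts,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

.inside_ellipsoid <- function(p, semi, center = c(0, 0, 0)) {
  ((p[, 1] - center[1]) / semi[1])^2 + ((p[, 2] - center[2]) / semi[2])^2 +
    ((p[, 3] - center[3]) / semi[3])^2 <= 1
}

# canonical (undeformed, unposed) inside test for the myocardium
.phantom_inside <- function(spec, p) {
  out <- spec$lv_outer_radii
  inn <- out - spec$wall_thickness
  zb <- spec$base_height
  fg <- .inside_ellipsoid(p, out) & !.inside_ellipsoid(p, inn) &
    p[, 3] <= zb
  if (identical(spec$topology, "BiV")) {
    # RV ellipsoid centre below the base so the cavity opens at the base
    # plane; its apex stays above the LV apex for default dimensions
    ctr <- c(spec$rv_center_offset, 0, zb - 0.8 * spec$rv_size[3])
    rv_out <- spec$rv_size
    rv_in <- spec$rv_size - spec$rv_wall_thickness
    rv <- .inside_ellipsoid(p, rv_out, ctr) &
      !.inside_ellipsoid(p, rv_in, ctr) &
      !.inside_ellipsoid(p, out) & p[, 3] <= zb
    fg <- fg | rv
  }
  fg
}

# forward/inverse deformation maps (canonical -> deformed)
.deform_maps <- function(def) {
  if (is.null(def))
    return(list(fwd = identity, inv = identity))
  if (identical(def$type, "affine")) {
    A <- def$A; b <- if (is.null(def$b)) c(0, 0, 0) else def$b
    Ai <- solve(A)
    list(fwd = function(p) sweep(p %*% t(A), 2, b, `+`),
         inv = function(p) sweep(p, 2, b, `-`) %*% t(Ai))
  } else if (identical(def$type, "bump")) {
    ax <- def$axis; al <- def$along
    amp <- def$amplitude; wl <- def$wavelength
    fwd <- function(p) {
      q <- p
      q[, ax] <- q[, ax] + amp * sin(2 * pi * p[, al] / wl)
      q
    }
    inv <- function(p) {
      q <- p
      for (i in 1:25)
        q[, ax] <- p[, ax] - amp * sin(2 * pi * q[, al] / wl)
      q
    }
    list(fwd = fwd, inv = inv)
  } else stop("unknown deformation type: ", def$type)
}

.pose_maps <- function(pose) {
  if (is.null(pose)) return(list(fwd = identity, inv = identity))
  R <- pose$R; t <- if (is.null(pose$t)) c(0, 0, 0) else pose$t
  list(fwd = function(p) sweep(p %*% t(R), 2, t, `+`),
       inv = function(p) sweep(p, 2, t, `-`) %*% R)
}

#' Generate a phantom binary mask with analytic ground truth
#'
#' A voxel is foreground iff its centre lies inside the (optionally
#' deformed, rigidly posed) truncated-ellipsoid shell; the test is analytic,
#' independent of any mesh rasterization. Deterministic for a fixed spec.
#'
#' @param spec a [phantom_spec()].
#' @param grid optional explicit grid (list with `dims`, `spacing`,
#'   `origin`, or a [binary_mask()]); default: tight bounding box plus
#'   margin.
#' @return list with `mask` (a [binary_mask()]) and `truth` (forward and
#'   inverse world maps, canonical spec, shell volume).
#' @export
generate_mask <- function(spec, grid = NULL) {
  if (spec$wall_thickness < max(spec$spacing))
    warning("wall thinner than voxel spacing")
  dm <- .deform_maps(spec$deformation)
  pm <- .pose_maps(spec$pose)
  out <- spec$lv_outer_radii
  ext <- c(max(out[1], if (identical(spec$topology, "BiV"))
                 spec$rv_center_offset + spec$rv_size[1] else 0),
           max(out[2], spec$rv_size[2]), out[3])
  if (is.null(grid)) {
    corners <- as.matrix(expand.grid(x = c(-ext[1], ext[1]),
                                     y = c(-ext[2], ext[2]),
                                     z = c(-ext[3], spec$base_height)))
    wc <- pm$fwd(dm$fwd(corners))
    lo <- apply(wc, 2, min) - spec$margin_mm
    hi <- apply(wc, 2, max) + spec$margin_mm
    dims <- as.integer(unname(pmax(ceiling((hi - lo) / spec$spacing) + 1L,
                                   4L)))
    origin <- unname(lo)
  } else {
    if (inherits(grid, "binary_mask"))
      grid <- list(dims = dim(grid$voxels), spacing = grid$spacing,
                   origin = grid$origin)
    if (any(abs(grid$spacing - spec$spacing) > 1e-9))
      spec$spacing <- rep(as.numeric(grid$spacing), length.out = 3)
    dims <- as.integer(grid$dims)
    origin <- as.numeric(grid$origin)
  }
  idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1L), j = 0:(dims[2] - 1L),
                               k = 0:(dims[3] - 1L)))
  pts <- sweep(sweep(idx, 2, spec$spacing, `*`), 2, origin, `+`)
  canon <- dm$inv(pm$inv(pts))
  fg <- .phantom_inside(spec, canon)
  vox <- array(fg, dims)
  mask <- binary_mask(vox, spacing = spec$spacing, origin = origin)
  if (!is.null(spec$interslice_distance))
    mask <- sparsify(mask, spec$interslice_distance)
  if (!is.null(spec$slice_shifts))
    mask <- apply_slice_shift(mask, spec$slice_shifts)
  truth <- list(
    spec = spec,
    canonical_to_world = function(p) pm$fwd(dm$fwd(p)),
    world_to_canonical = function(p) dm$inv(pm$inv(p)),
    shell_volume = .phantom_volume(spec)
  )
  list(mask = mask, truth = truth)
}

# analytic canonical shell volume (LV part exact; BiV adds the RV crescent
# by high-resolution numeric integration of the analytic inside test)
.phantom_volume <- function(spec) {
  v_lv <- truncated_shell_volume(spec$lv_outer_radii, spec$wall_thickness,
                                 spec$base_height)
  if (identical(spec$topology, "LV")) return(v_lv)
  # Monte-Carlo-free: fine-grid quadrature of the RV crescent only
  h <- 0.5
  ctr_x <- spec$rv_center_offset
  xr <- seq(ctr_x - spec$rv_size[1], ctr_x + spec$rv_size[1], by = h)
  yr <- seq(-spec$rv_size[2], spec$rv_size[2], by = h)
  zb <- spec$base_height
  zr <- seq(zb - 2 * spec$rv_size[3], zb, by = h)
  g <- as.matrix(expand.grid(x = xr, y = yr, z = zr))
  lv_only <- spec; lv_only$topology <- "LV"
  n_rv <- sum(.phantom_inside(spec, g) & !.phantom_inside(lv_only, g))
  v_lv + n_rv * h^3
}

#' Write a phantom to disk (NIfTI mask + JSON ground truth)
#'
#' The mask goes to `<path>.nii.gz`; the generating parameters and the
#' analytic shell volume go to `<path>_truth.json` (analytic map closures
#' are reproducible from the spec, which is serialized in full).
#'
#' @param ph result of [generate_mask()].
#' @param path output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_phantom <- function(ph, path) {
  img <- paste0(path, ".nii.gz")
  js <- paste0(path, "_truth.json")
  write_nifti(ph$mask, img)
  spec <- ph$truth$spec
  spec$pose <- if (is.null(spec$pose)) NULL
               else list(R = as.vector(spec$pose$R), t = spec$pose$t)
  jsonlite::write_json(list(spec = spec,
                            shell_volume = ph$truth$shell_volume,
                            data_slices = ph$mask$data_slices),
                       js, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(c(img, js))
}

#' Sparsify a mask to a short-axis-like slice stack
#'
#' Keeps slices spaced `interslice_distance` apart along `axis`; all other
#' slices are zeroed ("null intensity") and the kept indices are recorded in
#' `data_slices`, mirroring sparse dynamic MRI acquisitions.
#'
#' @param mask a [binary_mask()].
#' @param interslice_distance distance between retained slices (mm).
#' @param axis slice-stack axis (default 3).
#' @return a [binary_mask()] with `data_slices` set.
#' @export
sparsify <- function(mask, interslice_distance, axis = 3L) {
  dz <- mask$spacing[axis]
  if (interslice_distance < dz)
    stop("interslice distance below the axial spacing")
  r <- max(1L, round(interslice_distance / dz))
  n <- dim(mask$voxels)[axis]
  keep <- seq(1L, n, by = r)
  if (length(keep) < 3L) stop("fewer than 3 retained slices")
  if (r == 1L)
    return(binary_mask(mask$voxels, mask$spacing, mask$origin,
                       data_slices = keep, slice_axis = axis))
  vox <- mask$voxels
  drop_idx <- setdiff(seq_len(n), keep)
  if (axis == 1L) vox[drop_idx, , ] <- FALSE
  else if (axis == 2L) vox[, drop_idx, ] <- FALSE
  else vox[, , drop_idx] <- FALSE
  binary_mask(vox, mask$spacing, mask$origin, data_slices = keep,
              slice_axis = axis)
}

#' Apply in-plane slice shifts (breath-hold misregistration)
#'
#' Each slice along the stack axis is translated in-plane by its shift
#' (rounded to whole voxels), emulating slice-shift artefacts of short-axis
#' acquisitions.
#'
#' @param mask a [binary_mask()].
#' @param shifts `n_slices x 2` matrix of in-plane shifts (mm); rows beyond
#'   `nrow(shifts)` are unshifted. A single row recycles to all slices.
#' @param axis slice-stack axis (default 3).
#' @return shifted [binary_mask()].
#' @export
apply_slice_shift <- function(mask, shifts, axis = 3L) {
  d <- dim(mask$voxels)
  inplane <- setdiff(1:3, axis)
  shifts <- matrix(shifts, ncol = 2)
  fov <- d[inplane] * mask$spacing[inplane]
  if (any(abs(shifts) > fov[col(shifts)]))
    stop("shift larger than the field of view")
  vox <- mask$voxels
  n <- d[axis]
  roll <- function(m, by) {
    # integer-voxel 2-D shift with zero fill
    if (all(by == 0L)) return(m)
    out <- array(FALSE, dim(m))
    src1 <- seq_len(dim(m)[1]) - by[1]
    src2 <- seq_len(dim(m)[2]) - by[2]
    ok1 <- src1 >= 1 & src1 <= dim(m)[1]
    ok2 <- src2 >= 1 & src2 <= dim(m)[2]
    out[which(ok1), which(ok2)] <- m[src1[ok1], src2[ok2]]
    out
  }
  for (s in seq_len(n)) {
    sh <- if (s <= nrow(shifts)) shifts[s, ] else c(0, 0)
    by <- as.integer(round(sh / mask$spacing[inplane]))
    if (all(by == 0L)) next
    sl <- switch(axis, vox[s, , ], vox[, s, ], vox[, , s])
    sl <- roll(sl, by)
    if (axis == 1L) vox[s, , ] <- sl
    else if (axis == 2L) vox[, s, ] <- sl
    else vox[, , s] <- sl
  }
  binary_mask(vox, mask$spacing, mask$origin, data_slices = mask$data_slices,
              slice_axis = mask$slice_axis)
}

#' Seeded random phantom cohort
#'
#' Draws `n` phantom specs with radii, thickness and rigid pose sampled
#' uniformly in the stated ranges; reproducible for a fixed seed and
#' independent of the caller's RNG state.
#'
#' @param n cohort size.
#' @param base_spec a [phantom_spec()] providing centre values.
#' @param variation list: `radii_frac` (default 0.2), `thickness_frac`
#'   (0.3), `tilt_deg` (20), `trans_mm` (5).
#' @param seed integer seed.
#' @return list of `n` [phantom_spec()] objects.
#' @export
random_cohort <- function(n, base_spec,
                          variation = list(radii_frac = 0.2,
                                           thickness_frac = 0.3,
                                           tilt_deg = 20, trans_mm = 5),
                          seed = 1L) {
  stopifnot(n >= 1)
  v <- utils::modifyList(list(radii_frac = 0.2, thickness_frac = 0.3,
                              tilt_deg = 20, trans_mm = 5), variation)
  if (v$radii_frac < 0 || v$thickness_frac < 0 || v$tilt_deg < 0)
    stop("invalid variation ranges")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    radii <- base_spec$lv_outer_radii *
      stats::runif(3, 1 - v$radii_frac, 1 + v$radii_frac)
    th <- base_spec$wall_thickness *
      stats::runif(1, 1 - v$thickness_frac, 1 + v$thickness_frac)
    th <- min(th, 0.6 * min(radii))
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, 0, v$tilt_deg) * pi / 180
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    tr <- stats::runif(3, -v$trans_mm, v$trans_mm)
    sp <- base_spec
    sp$lv_outer_radii <- radii
    sp$wall_thickness <- th
    sp$base_height <- base_spec$base_height / base_spec$lv_outer_radii[3] *
      radii[3]
    sp$pose <- list(R = R, t = tr)
    sp$seed <- as.integer(seed + i)
    specs[[i]] <- sp
  }
  specs
}
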