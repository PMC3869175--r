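# Multi-pass control-grid non-rigid registration of binary images under the
# level-of-detail schedule; functional replacement for a black-box
# registration engine. Each pass optimizes displacements stored on a
# regular control lattice (trilinear tent interpolation to the voxel grid)
# against the sum of squared differences between Gaussian-smoothed binary
# images, with a second-difference (bending-energy-style) smoothness
# penalty; passes warm-start from the previous pass. The optimization runs
# in fixed-image space (w maps fixed -> moving), so a sparse-slice domain
# restriction is well posed; the returned field (moving/template ->
# fixed/target) is the fixed-point inverse of w.

#' Level-of-detail schedule
#'
#' LoD 1..5 gives 1..5 registration passes with control-node spacing
#' decreasing from 10 to 2 voxels in steps of 2: pass spacings are the
#' first `lod` entries of (10, 8, 6, 4, 2).
#'
#' @param lod integer 1..5.
#' @param node_spacings optional override of the spacing sequence.
#' @return list of class `lod_config` with `lod`, `passes`, `node_spacings`.
#' @export
lod_schedule <- function(lod, node_spacings = NULL) {
  lod <- as.integer(lod)
  if (length(lod) != 1L || is.na(lod) || lod < 1L || lod > 5L)
    stop("lod must be an integer in 1..5")
  sched <- c(10L, 8L, 6L, 4L, 2L)
  sp <- if (is.null(node_spacings)) sched[seq_len(lod)]
        else as.integer(node_spacings)
  structure(list(lod = lod, passes = length(sp), node_spacings = sp),
            class = "lod_config")
}

# trilerp of a (nx,ny,nz,3) field at pts (n x 3, 0-based voxel coords)
.field_trilerp <- function(C, pts) {
  d <- dim(C)
  cbind(.c_trilerp(C[, , , 1], d[1:3], pts),
        .c_trilerp(C[, , , 2], d[1:3], pts),
        .c_trilerp(C[, , , 3], d[1:3], pts))
}

# second differences along one axis of a 3-D array (values), and the
# adjoint application used for the regularizer gradient; both operate with
# the target axis permuted to the front
.d2_apply <- function(a, ax) {
  d <- dim(a)[1:3]
  n <- d[ax]
  if (n < 3L) return(matrix(0, 0, 0))
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(array(a, d), perm), nrow = n)
  m[1:(n - 2), , drop = FALSE] - 2 * m[2:(n - 1), , drop = FALSE] +
    m[3:n, , drop = FALSE]
}

.d2_adjoint <- function(r, ax, d) {
  n <- d[ax]
  perm <- c(ax, setdiff(1:3, ax))
  out <- matrix(0, n, prod(d[-ax]))
  if (n >= 3L) {
    out[1:(n - 2), ] <- out[1:(n - 2), ] + r
    out[2:(n - 1), ] <- out[2:(n - 1), ] - 2 * r
    out[3:n, ] <- out[3:n, ] + r
  }
  aperm(array(out, d[perm]), order(perm))
}

#' Non-rigid registration between two binary masks
#'
#' @param fixed target [binary_mask()]; the grid of `fixed` is the common
#'   grid (the moving image must live on the same grid).
#' @param moving template [binary_mask()] (after initial affine alignment).
#' @param config a [lod_schedule()] result.
#' @param domain optional logical array (fixed grid): voxels where the
#'   similarity is evaluated (sparse-slice registration).
#' @param sigma_vox Gaussian smoothing in voxels (default 1).
#' @param reg_weight smoothness penalty weight (default 0.05; calibrated so
#'   the identity case stays below 0.1 voxel and a pure translation is
#'   recovered within 0.5 voxel).
#' @param max_iter gradient-descent iterations per pass.
#' @param band_vox band half-width around the foreground outside which the
#'   returned field is tapered to zero.
#' @param sparse_axis slice-stack axis of a sparse fixed image (smoothing
#'   across the null slices is then disabled), or NULL.
#' @return object of class `displacement_field`: `u` (`nx x ny x nz x 3`,
#'   mm; maps template-space point x to target point x + u(x)), `spacing`,
#'   `origin`, plus per-pass SSD diagnostics.
#' @export
register <- function(fixed, moving, config = lod_schedule(3L),
                     domain = NULL, sigma_vox = 1, reg_weight = 0.05,
                     max_iter = 30L, band_vox = 15, sparse_axis = NULL) {
  d <- dim(fixed$voxels)
  if (!identical(d, dim(moving$voxels)))
    stop("fixed and moving masks must share one grid; resample first")
  if (!any(fixed$voxels & moving$voxels) &&
      !any(.dilate(fixed$voxels, fixed$spacing,
                   5 * max(fixed$spacing)) & moving$voxels))
    stop("no overlap between fixed and moving after affine alignment")
  # sparse stacks: smoothing across null slices would dilute the data
  # slices (their smoothed value drops far below the moving image's),
  # biasing the SSD; smooth the fixed image in-plane only
  sig_f <- rep(sigma_vox, 3)
  if (!is.null(sparse_axis)) sig_f[sparse_axis] <- 0
  Fm <- .gauss3(fixed$voxels * 1.0, sig_f)
  Mm <- .gauss3(moving$voxels * 1.0, sigma_vox)
  # gradient volumes of the moving image (central differences, voxel units)
  G <- array(0, c(d, 3))
  for (ax in 1:3) {
    n <- d[ax]
    hi <- pmin(seq_len(n) + 1L, n)
    lo <- pmax(seq_len(n) - 1L, 1L)
    den <- hi - lo
    if (ax == 1L) G[, , , 1] <- (Mm[hi, , ] - Mm[lo, , ]) / den
    else if (ax == 2L) G[, , , 2] <- (Mm[, hi, ] - Mm[, lo, ]) /
        rep(den, each = d[1])
    else G[, , , 3] <- (Mm[, , hi] - Mm[, , lo]) /
        rep(den, each = d[1] * d[2])
  }
  union_fg <- fixed$voxels | moving$voxels
  band_mm <- .edt_mm(union_fg, fixed$spacing)
  active <- band_mm <= 6 * max(fixed$spacing)
  if (!is.null(domain)) active <- active & domain
  P <- which(array(active, d), arr.ind = TRUE) - 1
  storage.mode(P) <- "double"
  Fp <- Fm[active]
  ssd0 <- sum((Mm[active] - Fp)^2)
  ssd_pass <- numeric(0)
  Cprev <- NULL
  sprev <- NULL
  for (s in config$node_spacings) {
    nc <- ceiling((d - 1) / s) + 3L  # one margin node each side
    Pc <- P / s + 1                  # control-space coordinates of voxels
    C <- array(0, c(nc, 3L))
    if (!is.null(Cprev)) {
      # warm start: sample previous control field at new control nodes
      gp <- as.matrix(expand.grid(i = 0:(nc[1] - 1L), j = 0:(nc[2] - 1L),
                                  k = 0:(nc[3] - 1L)))
      vox_of_node <- (gp - 1) * s          # voxel coords of new nodes
      old_coords <- vox_of_node / sprev + 1
      C <- array(.field_trilerp(Cprev, old_coords), c(nc, 3L))
    }
    n_dom <- nrow(P)
    n_ctrl <- prod(nc)
    lam <- reg_weight * n_dom / n_ctrl
    cost_fn <- function(C) {
      w <- .field_trilerp(C, Pc)
      y <- P + w
      r <- .c_trilerp(Mm, d, y) - Fp
      reg <- 0
      for (ax in 1:3) for (k in 1:3)
        reg <- reg + sum(.d2_apply(C[, , , k], ax)^2)
      list(cost = sum(r^2) + lam * reg, r = r, y = y)
    }
    grad_fn <- function(C, r, y) {
      gr <- array(0, c(nc, 3L))
      for (k in 1:3) {
        gk <- 2 * r * .c_trilerp(G[, , , k], d, y)
        gr[, , , k] <- array(.c_triscatter(nc, Pc, gk), nc)
      }
      for (ax in 1:3) for (k in 1:3) {
        r2 <- .d2_apply(C[, , , k], ax)
        if (length(r2))
          gr[, , , k] <- gr[, , , k] + 2 * lam * .d2_adjoint(r2, ax, nc)
      }
      gr
    }
    # gradient descent with backtracking line search and heavy-ball
    # momentum (restarted whenever the cost would increase); deterministic
    ev <- cost_fn(C)
    step <- NULL
    mom <- 0
    beta <- 0.85
    stall <- 0L
    for (it in seq_len(max_iter)) {
      gr <- grad_fn(C, ev$r, ev$y)
      gmax <- max(abs(gr))
      if (gmax < 1e-12) break
      if (is.null(step)) step <- 0.25 / gmax  # first move <= 1/4 voxel
      improved <- FALSE
      for (bt in 1:10) {
        dir <- beta * mom - step * gr
        Cn <- C + dir
        evn <- cost_fn(Cn)
        if (evn$cost < ev$cost) { improved <- TRUE; break }
        mom <- 0                    # momentum restart
        step <- step / 2
      }
      if (!improved) break
      rel <- (ev$cost - evn$cost) / max(ev$cost, 1e-12)
      mom <- dir
      C <- Cn
      ev <- evn
      step <- step * 1.3
      stall <- if (rel < 1e-5) stall + 1L else 0L
      if (stall >= 3L) break
    }
    Cprev <- C
    sprev <- s
    ssd_pass <- c(ssd_pass, sum(ev$r^2))
  }
  # dense forward field on the fixed grid (w: fixed -> moving, voxel units)
  gp <- which(array(TRUE, d), arr.ind = TRUE) - 1
  storage.mode(gp) <- "double"
  w_dense <- .field_trilerp(Cprev, gp / sprev + 1)
  # invert: u(x) with x + u(x) on the fixed image matching template point x
  u <- matrix(0, nrow(gp), 3)
  for (it in 1:10) {
    u <- -.interp_dense(w_dense, d, gp + u)
  }
  # taper to zero outside the band (band_mm is in gp's column-major order)
  bd <- as.numeric(band_mm) / max(fixed$spacing)
  taper <- pmax(pmin((band_vox - bd) / 5, 1), 0)
  u <- u * taper
  u_mm <- sweep(u, 2, fixed$spacing, `*`)
  structure(list(
    u = array(u_mm, c(d, 3L)), spacing = fixed$spacing,
    origin = fixed$origin, dims = d,
    ssd_initial = ssd0, ssd_pass = ssd_pass, config = config
  ), class = "displacement_field")
}

# interpolate an (n_all x 3) dense voxel-grid field at fractional coords
.interp_dense <- function(w_flat, d, pts) {
  cbind(.c_trilerp(array(w_flat[, 1], d), d, pts),
        .c_trilerp(array(w_flat[, 2], d), d, pts),
        .c_trilerp(array(w_flat[, 3], d), d, pts))
}

#' Sample a displacement field at world points
#'
#' Trilinear interpolation of the per-voxel displacement vectors; points
#' outside the grid clamp to the boundary value.
#'
#' @param field a `displacement_field` from [register()].
#' @param pts `n x 3` world coordinates (mm).
#' @return `n x 3` displacements (mm).
#' @export
field_at <- function(field, pts) {
  vox <- sweep(sweep(matrix(pts, ncol = 3), 2, field$origin, `-`), 2,
               field$spacing, `/`)
  d <- field$dims
  cbind(.c_trilerp(field$u[, , , 1], d, vox),
        .c_trilerp(field$u[, , , 2], d, vox),
        .c_trilerp(field$u[, , , 3], d, vox))
}

#' Export a displacement field as a NIfTI vector volume
#' @param field a `displacement_field`.
#' @param path output `.nii`/`.nii.gz` path.
#' @return invisibly, `path`.
#' @export
write_field_nifti <- function(field, path) {
  write_nifti(field$u, path, spacing = field$spacing, origin = field$origin)
}

#' Build the sparse-slice registration domain
#'
#' For a mask acquired as a sparse slice stack, builds a nearly isotropic
#' grid by inserting null-intensity slices between the data slices (when the
#' stored grid is coarse along the stack axis) and returns the voxel domain
#' covering exactly the data slices, which is where the registration
#' similarity is evaluated.
#'
#' @param mask a [binary_mask()] with `data_slices` set.
#' @return list with `mask` (near-isotropic grid, `data_slices` updated)
#'   and `domain` (logical array on that grid).
#' @export
build_sparse_domain <- function(mask) {
  if (is.null(mask$data_slices)) stop("mask has no data_slices")
  if (length(mask$data_slices) < 2L) stop("fewer than 2 data slices")
  ax <- mask$slice_axis
  inplane <- min(mask$spacing[setdiff(1:3, ax)])
  r <- max(1L, round(mask$spacing[ax] / inplane))
  out <- mask
  if (r > 1L) {
    # insert r-1 null slices between stored slices
    d <- dim(mask$voxels)
    nd <- d
    nd[ax] <- (d[ax] - 1L) * r + 1L
    vox <- array(FALSE, nd)
    sl_new <- (seq_len(d[ax]) - 1L) * r + 1L
    if (ax == 1L) vox[sl_new, , ] <- mask$voxels
    else if (ax == 2L) vox[, sl_new, ] <- mask$voxels
    else vox[, , sl_new] <- mask$voxels
    spacing <- mask$spacing
    spacing[ax] <- mask$spacing[ax] / r
    out <- binary_mask(vox, spacing, mask$origin,
                       data_slices = sl_new[mask$data_slices],
                       slice_axis = ax)
  }
  d <- dim(out$voxels)
  dom <- array(FALSE, d)
  if (ax == 1L) dom[out$data_slices, , ] <- TRUE
  else if (ax == 2L) dom[, out$data_slices, ] <- TRUE
  else dom[, , out$data_slices] <- TRUE
  list(mask = out, domain = dom)
}

#' Rasterize a Hermite mesh to a binary mask
#'
#' The mesh's external surface is subdivided into triangles and voxelized
#' by vertical ray parity: a voxel is foreground iff its centre lies inside
#' the closed surface. Deterministic.
#'
#' @param mesh a [hermite_mesh()] with labelled surface faces.
#' @param grid a [binary_mask()] (grid template) or list with `dims`,
#'   `spacing`, `origin`.
#' @param subdivision surface sampling density per face per axis.
#' @return a [binary_mask()] on the requested grid.
#' @export
rasterize_mesh <- function(mesh, grid, subdivision = 12L) {
  if (inherits(grid, "binary_mask"))
    grid <- list(dims = dim(grid$voxels), spacing = grid$spacing,
                 origin = grid$origin)
  faces <- do.call(rbind, mesh$surface_faces)
  if (is.null(faces) || !nrow(faces)) stop("mesh has no surface faces")
  s <- as.integer(subdivision)
  ticks <- seq(0, 1, length.out = s + 1L)
  st <- as.matrix(expand.grid(a = ticks, b = ticks))
  nvf <- nrow(st)
  verts <- matrix(0, nrow(faces) * nvf, 3)
  for (f in seq_len(nrow(faces))) {
    fa <- .face_axes(faces[f, 2])
    xi <- matrix(fa$val, nvf, 3)
    xi[, fa$free[1]] <- st[, 1]
    xi[, fa$free[2]] <- st[, 2]
    verts[(f - 1L) * nvf + seq_len(nvf), ] <-
      evaluate_element(mesh, faces[f, 1], xi)
  }
  # triangles within one face lattice
  quad <- matrix(0L, s * s, 4L)
  q <- 1L
  for (jb in 0:(s - 1L)) for (ia in 0:(s - 1L)) {
    v00 <- ia + (s + 1L) * jb
    quad[q, ] <- c(v00, v00 + 1L, v00 + s + 1L, v00 + s + 2L)
    q <- q + 1L
  }
  tri1 <- cbind(quad[, 1], quad[, 2], quad[, 4])
  tri0 <- cbind(quad[, 1], quad[, 4], quad[, 3])
  tris <- do.call(rbind, lapply(seq_len(nrow(faces)), function(f)
    rbind(tri0, tri1) + (f - 1L) * nvf))
  vcoord <- sweep(sweep(verts, 2, grid$origin, `-`), 2, grid$spacing, `/`)
  vox <- array(.c_voxelize_parity(vcoord, tris, as.integer(grid$dims)),
               grid$dims)
  if (!any(vox)) stop("rasterization produced an empty mask (degenerate mesh?)")
  binary_mask(vox, grid$spacing, grid$origin)
}
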