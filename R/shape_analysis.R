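# Shape analysis of a ventricular binary mask: blood pools and valve
# openings, basal plane, characteristic axes, dimensions and the initial
# affine alignment (pipeline step 1).

# Iterated slice-wise 2-D convex-hull fill along all three axes (to a fixed
# point, max `iter` sweeps). For ellipsoid-like shapes this equals the 3-D
# convex hull fill; it is a documented approximation for general shapes.
.convex_fill <- function(vox, iter = 4L) {
  d <- dim(vox)
  cur <- vox
  for (pass in seq_len(iter)) {
    before <- sum(cur)
    for (ax in 1:3) {
      n <- d[ax]
      for (s in seq_len(n)) {
        sl <- switch(ax, cur[s, , ], cur[, s, ], cur[, , s])
        fg <- which(sl, arr.ind = TRUE)
        if (nrow(fg) < 3L) next
        hull <- grDevices::chull(fg)
        hv <- fg[hull, , drop = FALSE]
        # candidate points: bounding box minus already-filled
        r1 <- range(hv[, 1]); r2 <- range(hv[, 2])
        cand <- as.matrix(expand.grid(i = r1[1]:r1[2], j = r2[1]:r2[2]))
        cand <- cand[!sl[cand], , drop = FALSE]
        if (!nrow(cand)) next
        m <- nrow(hv)
        inside <- rep(TRUE, nrow(cand))
        for (e in seq_len(m)) {
          p1 <- hv[e, ]; p2 <- hv[(e %% m) + 1L, ]
          cr <- (cand[, 1] - p1[1]) * (p2[2] - p1[2]) -
                (cand[, 2] - p1[2]) * (p2[1] - p1[1])
          inside <- inside & cr >= -1e-9  # chull returns clockwise order
          if (!any(inside)) break
        }
        if (any(inside)) {
          sl[cand[inside, , drop = FALSE]] <- TRUE
          if (ax == 1L) cur[s, , ] <- sl
          else if (ax == 2L) cur[, s, ] <- sl
          else cur[, , s] <- sl
        }
      }
    }
    if (sum(cur) == before) break
  }
  cur
}

# propagate component labels to unlabelled cavity voxels (6-neighbour flood)
.spread_labels <- function(lab, domain) {
  d <- dim(lab)
  for (it in 1:200) {
    changed <- FALSE
    for (ax in 1:3) for (dir in c(-1L, 1L)) {
      sh <- array(0L, d)
      n <- d[ax]
      src <- if (dir == 1L) 1:(n - 1) else 2:n
      dst <- if (dir == 1L) 2:n else 1:(n - 1)
      if (ax == 1L) sh[dst, , ] <- lab[src, , ]
      else if (ax == 2L) sh[, dst, ] <- lab[, src, ]
      else sh[, , dst] <- lab[, , src]
      upd <- domain & lab == 0L & sh > 0L
      if (any(upd)) { lab[upd] <- sh[upd]; changed <- TRUE }
    }
    if (!changed) break
  }
  lab
}

#' Identify blood pools and valve openings
#'
#' The cavity is the convex-hull fill of the mask minus the myocardium,
#' split into connected components; adaptive erosion separates components
#' that touch through thin bridges. The largest components are the LV and
#' (when present) RV blood pools — the LV is the pool with the larger
#' volume-to-surface ratio (more convex), ties broken by volume. Valve
#' voxels are cavity voxels reaching the hull boundary (the openings).
#'
#' @param mask a [binary_mask()].
#' @return list with `lv_pool`, `rv_pool` (logical arrays; `rv_pool` NULL
#'   for LV-only masks), `valve_voxels` (logical array), `cavity`, `hull`.
#' @export
find_pools_and_valves <- function(mask) {
  vox <- mask$voxels
  hull <- .convex_fill(vox)
  cavity <- hull & !vox
  if (!any(cavity))
    stop("no cavity found: the mask is a solid blob")
  min_pool <- max(64, round(0.02 * sum(cavity)))
  lab <- .label6(cavity)
  nbig <- sum(tabulate(lab[lab > 0L]) >= min_pool)
  if (nbig < 2L) {
    # try erosion to split pools joined through thin bridges
    for (r in 1:3) {
      er <- .erode(cavity, mask$spacing, r * min(mask$spacing))
      if (!any(er)) break
      lab_er <- .label6(er)
      nbig_er <- sum(tabulate(lab_er[lab_er > 0L]) >= min_pool)
      if (nbig_er >= 2L) {
        lab <- .spread_labels(lab_er, cavity)
        nbig <- nbig_er
        break
      }
    }
  }
  counts <- tabulate(lab[lab > 0L])
  big <- which(counts >= min_pool)
  big <- big[order(counts[big], decreasing = TRUE)][seq_len(min(2, length(big)))]
  pools <- lapply(big, function(b) array(lab == b, dim(vox)))
  if (length(pools) == 2L) {
    # LV = more convex pool: larger volume-to-surface ratio
    ratio <- vapply(pools, function(p) {
      surf <- sum(p & !.erode(p, mask$spacing, min(mask$spacing)))
      sum(p) / max(surf, 1)
    }, 0)
    if (abs(diff(ratio)) < 1e-9) ord <- order(vapply(pools, sum, 0),
                                              decreasing = TRUE)
    else ord <- order(ratio, decreasing = TRUE)
    pools <- pools[ord]
    lv_pool <- pools[[1]]; rv_pool <- pools[[2]]
  } else {
    lv_pool <- pools[[1]]; rv_pool <- NULL
  }
  # valves: cavity voxels with a 6-neighbour outside the hull
  outside <- !hull
  d <- dim(vox)
  touch <- array(FALSE, d)
  for (ax in 1:3) for (dir in c(-1L, 1L)) {
    sh <- array(TRUE, d)  # out-of-grid counts as outside
    n <- d[ax]
    src <- if (dir == 1L) 1:(n - 1) else 2:n
    dst <- if (dir == 1L) 2:n else 1:(n - 1)
    if (ax == 1L) sh[dst, , ] <- outside[src, , ]
    else if (ax == 2L) sh[, dst, ] <- outside[, src, ]
    else sh[, , dst] <- outside[, , src]
    touch <- touch | sh
  }
  # restrict to the main pools: the hull also bridges concave notches
  # (e.g. along the RV insertion), which are not openings
  pool_any <- lv_pool
  if (!is.null(rv_pool)) pool_any <- pool_any | rv_pool
  valve <- cavity & touch & pool_any
  list(lv_pool = lv_pool, rv_pool = rv_pool, valve_voxels = valve,
       cavity = cavity, hull = hull)
}

#' Total-least-squares basal plane through the valve voxels
#'
#' @param valve_voxels logical array of valve voxels (from
#'   [find_pools_and_valves()]).
#' @param spacing,origin grid geometry (mm).
#' @param mask optional [binary_mask()] used to orient the normal toward the
#'   apex-free (valve) side.
#' @return list with `point` (mm) and unit `normal`; the normal points away
#'   from the myocardial mass.
#' @export
fit_basal_plane <- function(valve_voxels, spacing, origin, mask = NULL) {
  idx <- which(valve_voxels, arr.ind = TRUE) - 1L
  if (nrow(idx) < 3L) stop("need at least 3 valve voxels")
  pts <- sweep(sweep(idx, 2, spacing, `*`), 2, origin, `+`)
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  if (ev$values[2] < 1e-8 * max(ev$values[1], 1))
    stop("valve voxels are collinear; cannot fit a plane")
  normal <- ev$vectors[, 3]
  if (!is.null(mask)) {
    fg <- .vox_to_world(.mask_fg_idx0(mask), mask)
    if (sum(normal * (ctr - colMeans(fg))) < 0) normal <- -normal
  }
  list(point = ctr, normal = normal / sqrt(sum(normal^2)))
}

#' Characteristic axes of the ventricular anatomy
#'
#' The long axis is the basal-plane normal (or the slice normal for sparse
#' stacks with `data_slices`); the left-right axis is the in-plane
#' projection of the LV-to-RV centroid vector (LV-only masks: the larger
#' in-plane principal inertia axis of the myocardium); the third axis
#' completes a right-handed orthonormal frame.
#'
#' @param mask a [binary_mask()].
#' @param pools result of [find_pools_and_valves()].
#' @param plane result of [fit_basal_plane()].
#' @return list with `axis_long`, `axis_lr`, `axis_third` (orthonormal,
#'   right-handed) plus the pool centroids (mm).
#' @export
compute_axes <- function(mask, pools, plane) {
  if (!is.null(mask$data_slices)) {
    n <- c(0, 0, 0)
    n[mask$slice_axis] <- 1
    if (!is.null(plane) && sum(n * plane$normal) < 0) n <- -n
    axis_long <- n
  } else axis_long <- plane$normal
  lv_c <- colMeans(.vox_to_world(which(pools$lv_pool, arr.ind = TRUE) - 1L,
                                 mask))
  rv_c <- NULL
  if (!is.null(pools$rv_pool)) {
    rv_c <- colMeans(.vox_to_world(which(pools$rv_pool, arr.ind = TRUE) - 1L,
                                   mask))
    v <- rv_c - lv_c
    v <- v - sum(v * axis_long) * axis_long
    if (sqrt(sum(v^2)) < 1e-9)
      stop("LV-to-RV vector is parallel to the long axis")
    axis_lr <- v / sqrt(sum(v^2))
  } else {
    fg <- .vox_to_world(.mask_fg_idx0(mask), mask)
    cc <- sweep(fg, 2, colMeans(fg))
    P <- diag(3) - tcrossprod(axis_long)   # in-plane projector
    M <- P %*% (crossprod(cc) / nrow(cc)) %*% P
    ev <- eigen(M, symmetric = TRUE)
    axis_lr <- ev$vectors[, 1]
    axis_lr <- axis_lr - sum(axis_lr * axis_long) * axis_long
    axis_lr <- axis_lr / sqrt(sum(axis_lr^2))
  }
  axis_third <- c(axis_long[2] * axis_lr[3] - axis_long[3] * axis_lr[2],
                  axis_long[3] * axis_lr[1] - axis_long[1] * axis_lr[3],
                  axis_long[1] * axis_lr[2] - axis_long[2] * axis_lr[1])
  axis_third <- axis_third / sqrt(sum(axis_third^2))
  list(axis_long = axis_long, axis_lr = axis_lr, axis_third = axis_third,
       lv_centroid = lv_c, rv_centroid = rv_c)
}

#' Measure cavity dimensions, wall thickness and scaling factors
#'
#' Sizes are variance-derived ellipsoid semi-axes: semi-axis = sqrt(5) x
#' standard deviation of the pool coordinates along each characteristic
#' axis (the exact relation for a uniform solid ellipsoid). Wall thickness
#' is a distance-transform ridge estimate (twice the 95th percentile of the
#' distance-to-background over the myocardium). The RV insertion level is
#' the RV long-axis extent relative to the LV foreground extent.
#'
#' @param mask a [binary_mask()].
#' @param descriptor partial descriptor with axes, centroids, basal plane
#'   and pools.
#' @return completed shape descriptor (class `shape_descriptor`).
#' @export
measure_dimensions <- function(mask, descriptor) {
  ax <- cbind(descriptor$axis_lr, descriptor$axis_third,
              descriptor$axis_long)
  lv_pts <- .vox_to_world(which(descriptor$lv_pool, arr.ind = TRUE) - 1L,
                          mask)
  lv_loc <- sweep(lv_pts, 2, descriptor$lv_centroid) %*% ax
  lv_size <- sqrt(5) * apply(lv_loc, 2, stats::sd)
  fg <- .vox_to_world(.mask_fg_idx0(mask), mask)
  fg_long <- fg %*% descriptor$axis_long
  plane_off <- sum(descriptor$basal_plane$point * descriptor$axis_long)
  lv_extent_long <- plane_off - min(fg_long)
  # equator: long-axis station of maximal in-plane width of the foreground
  rel <- sweep(fg, 2, descriptor$lv_centroid)
  long_c <- rel %*% descriptor$axis_long
  inplane <- sqrt(rowSums((rel - long_c %*% t(descriptor$axis_long))^2))
  brks <- seq(min(long_c) - 1e-9, max(long_c) + 1e-9, length.out = 41)
  bin <- cut(long_c, brks, labels = FALSE)
  prof <- vapply(seq_len(40), function(b) {
    v <- inplane[bin == b]
    if (length(v)) stats::quantile(v, 0.99, names = FALSE) else 0
  }, 0)
  prof <- stats::filter(prof, rep(1 / 5, 5), sides = 2)
  prof[is.na(prof)] <- 0
  ctrs <- (brks[-1] + brks[-41]) / 2
  z_eq_rel <- ctrs[which.max(prof)]
  z_eq <- sum(descriptor$lv_centroid * descriptor$axis_long) + z_eq_rel
  equator_offset <- max(plane_off - z_eq, 0)
  sparse <- !is.null(mask$data_slices) &&
    mask$spacing[mask$slice_axis] >
      1.5 * min(mask$spacing[setdiff(1:3, mask$slice_axis)])
  if (!sparse) {
    # wall thickness: distance-transform ridge
    dist_bg <- .edt_mm(!mask$voxels, mask$spacing)
    wall_thickness <- 2 * stats::quantile(dist_bg[mask$voxels], 0.95,
                                          names = FALSE)
  } else {
    # sparse stacks: the 3-D distance ridge is corrupted by the apex cap
    # slice (solid disc) and the coarse axial spacing; use the in-plane
    # difference between foreground and cavity half-widths at the equator
    # one-sided, on the -lr side (away from the RV free wall)
    fg_lr <- rel %*% descriptor$axis_lr
    cav_lr <- lv_loc[, 1]
    wall_thickness <- max(stats::quantile(-fg_lr, 0.99, names = FALSE) -
                            stats::quantile(-cav_lr, 0.99, names = FALSE),
                          2 * min(mask$spacing))
    # The axial extent is quantized by the interslice distance; recover the
    # long semi-axis from the accurate in-plane widths instead: for an
    # ellipsoid W(z)^2 is quadratic in z, so fit W^2 = alpha + beta z +
    # gamma z^2 over the data slices and read off apex and equator.
    ax_sl <- mask$slice_axis
    sl_idx0 <- round((fg[, ax_sl] - mask$origin[ax_sl]) /
                       mask$spacing[ax_sl])
    fg_lr_all <- rel %*% descriptor$axis_lr
    ok <- FALSE
    sl_u <- sort(unique(sl_idx0))
    if (length(sl_u) >= 4L) {
      zi <- wi <- numeric(length(sl_u))
      for (q in seq_along(sl_u)) {
        sel <- sl_idx0 == sl_u[q]
        zi[q] <- mean(long_c[sel] )
        wi[q] <- stats::quantile(-fg_lr_all[sel], 0.99, names = FALSE)
      }
      keep <- wi > 0
      if (sum(keep) >= 4L) {
        cf <- stats::coef(stats::lm(I(wi[keep]^2) ~ zi[keep] +
                                      I(zi[keep]^2)))
        gamma <- cf[3]; beta <- cf[2]; alpha <- cf[1]
        if (is.finite(gamma) && gamma < 0) {
          a2 <- alpha - beta^2 / (4 * gamma)
          c2 <- -a2 / gamma
          z0 <- -beta / (2 * gamma)
          if (a2 > 0 && c2 > 0) {
            z_apex <- z0 - sqrt(c2)
            z0_w <- z0 + sum(descriptor$lv_centroid * descriptor$axis_long)
            za_w <- z_apex + sum(descriptor$lv_centroid *
                                   descriptor$axis_long)
            lv_extent_long <- max(plane_off - za_w,
                                  lv_extent_long)
            equator_offset <- min(max(plane_off - z0_w, 0),
                                  0.45 * lv_extent_long)
            ok <- TRUE
          }
        }
      }
    }
    if (!ok) {
      # fallback: half-gap apex correction + canonical proportion
      lv_extent_long <- lv_extent_long + mask$spacing[ax_sl] / 2
      equator_offset <- 0.26 * lv_extent_long
    }
  }
  descriptor$lv_size <- as.numeric(lv_size)
  descriptor$scaling <- as.numeric(lv_size)
  descriptor$wall_thickness <- wall_thickness
  descriptor$lv_extent_long <- lv_extent_long
  descriptor$equator_offset <- equator_offset
  if (!is.null(descriptor$rv_pool)) {
    rv_pts <- .vox_to_world(which(descriptor$rv_pool, arr.ind = TRUE) - 1L,
                            mask)
    rv_loc <- sweep(rv_pts, 2, descriptor$rv_centroid) %*% ax
    descriptor$rv_size <- sqrt(5) * apply(rv_loc, 2, stats::sd)
    rv_rel <- sweep(rv_pts, 2, descriptor$lv_centroid) %*% ax
    descriptor$rv_extent <- apply(rv_rel, 2, function(v) diff(range(v)))
    rv_long <- rv_pts %*% descriptor$axis_long
    descriptor$rv_insertion_level <-
      (plane_off - min(rv_long)) / lv_extent_long
    ang <- atan2(rv_rel[, 2], rv_rel[, 1])
    descriptor$rv_angle <- diff(stats::quantile(ang, c(0.02, 0.98),
                                                names = FALSE))
  }
  class(descriptor) <- "shape_descriptor"
  descriptor
}

#' Truncate basal anatomy below the basal plane
#'
#' Removes foreground voxels on the valve side of the basal plane shifted
#' `offset_mm` toward the apex (the default 5 mm trims the valve anatomy so
#' the mask matches the flat-base template topology).
#'
#' @param mask a [binary_mask()].
#' @param plane basal plane from [fit_basal_plane()].
#' @param offset_mm apex-ward truncation offset (mm).
#' @return truncated [binary_mask()].
#' @export
truncate_base <- function(mask, plane, offset_mm = 5) {
  idx <- .mask_fg_idx0(mask)
  pts <- .vox_to_world(idx, mask)
  s <- sweep(pts, 2, plane$point) %*% plane$normal
  drop <- s > -offset_mm
  if (sum(drop) > 0.5 * nrow(idx))
    stop("basal truncation would remove more than half of the mask")
  vox <- mask$voxels
  vox[idx[drop, , drop = FALSE] + 1L] <- FALSE
  binary_mask(vox, mask$spacing, mask$origin,
              data_slices = mask$data_slices, slice_axis = mask$slice_axis)
}

#' Full shape analysis of a binary mask
#'
#' Convenience orchestration of [find_pools_and_valves()],
#' [fit_basal_plane()], [compute_axes()] and [measure_dimensions()].
#'
#' @param mask a [binary_mask()].
#' @return a `shape_descriptor`.
#' @export
analyze_shape <- function(mask) {
  pools <- find_pools_and_valves(mask)
  if (!any(pools$valve_voxels))
    stop("no valve opening found (closed shell); cannot fit basal plane")
  plane <- fit_basal_plane(pools$valve_voxels, mask$spacing, mask$origin,
                           mask)
  if (!is.null(mask$data_slices)) {
    # sparse stacks: the long axis is the slice normal by definition, and a
    # TLS plane through few coarse slices tilts unreliably -- snap the
    # basal-plane normal to the slice normal (sign kept)
    n <- c(0, 0, 0)
    n[mask$slice_axis] <- if (plane$normal[mask$slice_axis] < 0) -1 else 1
    plane$normal <- n
  }
  axes <- compute_axes(mask, pools, plane)
  descriptor <- c(axes, list(basal_plane = plane, lv_pool = pools$lv_pool,
                             rv_pool = pools$rv_pool,
                             valve_voxels = pools$valve_voxels,
                             topology = if (is.null(pools$rv_pool)) "LV"
                                        else "BiV"))
  measure_dimensions(mask, descriptor)
}

#' Initial affine alignment between two shape descriptors
#'
#' Composition of rotation (characteristic axis frames), anisotropic
#' scaling (ratio of scaling factors) and translation (LV centroids),
#' mapping template-space points onto target-space points.
#'
#' @param template_descriptor,target_descriptor shape descriptors.
#' @return list with `A` (3x3, positive determinant) and `b` (translation,
#'   mm); apply as `x -> A x + b`.
#' @export
initial_affine <- function(template_descriptor, target_descriptor) {
  frame <- function(d) {
    R <- cbind(d$axis_lr, d$axis_third, d$axis_long)
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      stop("descriptor axes are not orthonormal")
    R
  }
  R1 <- frame(template_descriptor)
  R2 <- frame(target_descriptor)
  s <- target_descriptor$scaling / template_descriptor$scaling
  A <- R2 %*% diag(s) %*% t(R1)
  b <- target_descriptor$lv_centroid -
    as.numeric(A %*% template_descriptor$lv_centroid)
  list(A = A, b = b)
}

#' Apply an affine transform to a Hermite mesh
#'
#' Positions map as `x -> A x + b`; all derivative DOFs map through the
#' linear part `A`.
#'
#' @param mesh a [hermite_mesh()].
#' @param affine list with `A` and `b` (as from [initial_affine()]).
#' @return transformed [hermite_mesh()].
#' @export
transform_mesh <- function(mesh, affine) {
  A <- affine$A; b <- affine$b
  dofs <- mesh$dofs
  n <- dim(dofs)[1]
  for (d in 1:8) {
    block <- matrix(dofs[, d, ], n, 3)
    block <- block %*% t(A)
    if (d == 1L) block <- sweep(block, 2, b, `+`)
    dofs[, d, ] <- block
  }
  mesh$dofs <- dofs
  mesh
}
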