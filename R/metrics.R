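# Mesh quality (Jacobian ratio), fitting accuracy (isosurface-to-surface
# distance), the success criterion, and transmural linearization.

#' Per-element Jacobian ratio
#'
#' Quality of one element: the ratio min_i det J_i / max_i det J_i over the
#' element's interior Gauss quadrature points — the homogeneity of the
#' volume differential. 1 for affine elements; approaches 0 for skewed or
#' collapsed elements. A non-positive det J at any quadrature point returns
#' 0 with attribute `inverted = TRUE`.
#'
#' @param mesh a [hermite_mesh()].
#' @param element_id element index.
#' @param quad_order Gauss points per axis (strictly interior, so the
#'   collapsed apex stays finite).
#' @return scalar in \[0, 1\].
#' @export
jacobian_ratio <- function(mesh, element_id, quad_order = 4L) {
  q <- .gauss_cube(quad_order)
  detj <- element_jacobian(mesh, element_id, q$xi)$det
  if (any(detj <= 0)) {
    out <- 0
    attr(out, "inverted") <- TRUE
    return(out)
  }
  min(detj) / max(detj)
}

#' Aggregate mesh quality
#'
#' Minimum and mean of the per-element Jacobian ratios. The success
#' criterion compares the mean against the empirical 0.33 threshold: with
#' collapsed apex elements present the minimum is structurally near zero
#' (det J vanishes towards the collapsed face), so the per-mesh quality
#' quoted against the threshold is the average Jacobian ratio.
#'
#' @param mesh a [hermite_mesh()].
#' @param quad_order Gauss points per axis.
#' @return list with `min`, `mean`, `per_element`.
#' @export
mesh_quality <- function(mesh, quad_order = 4L) {
  q <- vapply(seq_len(nrow(mesh$elements)), function(e)
    as.numeric(jacobian_ratio(mesh, e, quad_order)), 0)
  list(min = min(q), mean = mean(q), per_element = q)
}

#' Isosurface vertices of a binary mask
#'
#' The 0.5-level marching-cubes vertices of a binary image lie at the
#' midpoints of grid edges joining a foreground and a background voxel
#' (the linear-interpolation crossing); this function returns exactly that
#' vertex set, in world mm. The triangulation itself is not needed for
#' point-to-surface distances.
#'
#' @param mask a [binary_mask()].
#' @return `n x 3` matrix of vertex positions (mm).
#' @export
isosurface_vertices <- function(mask) {
  v <- mask$voxels
  d <- dim(v)
  verts <- list()
  for (ax in 1:3) {
    n <- d[ax]
    if (ax == 1L) x <- v[1:(n - 1), , ] != v[2:n, , ]
    else if (ax == 2L) x <- v[, 1:(n - 1), ] != v[, 2:n, ]
    else x <- v[, , 1:(n - 1)] != v[, , 2:n]
    idx <- which(x, arr.ind = TRUE) - 1L
    if (!nrow(idx)) next
    idx <- idx * 1.0
    idx[, ax] <- idx[, ax] + 0.5
    verts[[ax]] <- idx
  }
  pts <- do.call(rbind, verts)
  if (is.null(pts) || !nrow(pts)) stop("mask yields no isosurface")
  sweep(sweep(pts, 2, mask$spacing, `*`), 2, mask$origin, `+`)
}

# dense sampling of the mesh external surface: points + their (face, s, t)
.surface_samples <- function(mesh, face_set = NULL, sub = 8L) {
  faces <- if (is.null(face_set)) do.call(rbind, mesh$surface_faces)
           else face_set
  ticks <- seq(0, 1, length.out = sub + 1L)
  st <- as.matrix(expand.grid(a = ticks, b = ticks))
  nvf <- nrow(st)
  pts <- matrix(0, nrow(faces) * nvf, 3)
  for (f in seq_len(nrow(faces))) {
    fa <- .face_axes(faces[f, 2])
    xi <- matrix(fa$val, nvf, 3)
    xi[, fa$free[1]] <- st[, 1]
    xi[, fa$free[2]] <- st[, 2]
    pts[(f - 1L) * nvf + seq_len(nvf), ] <-
      evaluate_element(mesh, faces[f, 1], xi)
  }
  list(points = pts, faces = faces,
       face_of = rep(seq_len(nrow(faces)), each = nvf),
       st = st[rep(seq_len(nvf), nrow(faces)), , drop = FALSE])
}

# Newton (Gauss-Newton) refinement of closest points on bicubic faces.
# query: n x 3; seed face index + (s,t) per query. Returns distances.
.closest_point_newton <- function(mesh, faces, query, face_idx, st,
                                  max_iter = 50L, tol = 1e-8) {
  n <- nrow(query)
  s <- st[, 1]; t <- st[, 2]
  active <- rep(TRUE, n)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    for (f in unique(face_idx[active])) {
      sel <- which(active & face_idx == f)
      fa <- .face_axes(faces[f, 2])
      xi <- matrix(fa$val, length(sel), 3)
      xi[, fa$free[1]] <- s[sel]
      xi[, fa$free[2]] <- t[sel]
      jac <- element_jacobian(mesh, faces[f, 1], xi)
      pos <- evaluate_element(mesh, faces[f, 1], xi)
      if (is.null(dim(pos))) pos <- matrix(pos, 1, 3)
      r <- query[sel, , drop = FALSE] - pos
      t1 <- matrix(jac$J[, , fa$free[1]], length(sel), 3)
      t2 <- matrix(jac$J[, , fa$free[2]], length(sel), 3)
      a11 <- rowSums(t1 * t1); a12 <- rowSums(t1 * t2)
      a22 <- rowSums(t2 * t2)
      b1 <- rowSums(t1 * r); b2 <- rowSums(t2 * r)
      det <- a11 * a22 - a12^2
      det[abs(det) < 1e-14] <- 1e-14
      ds <- pmin(pmax((b1 * a22 - b2 * a12) / det, -0.25), 0.25)  # damped
      dt <- pmin(pmax((b2 * a11 - b1 * a12) / det, -0.25), 0.25)
      s_new <- pmin(pmax(s[sel] + ds, 0), 1)
      t_new <- pmin(pmax(t[sel] + dt, 0), 1)
      conv <- pmax(abs(s_new - s[sel]), abs(t_new - t[sel])) <= tol
      s[sel] <- s_new
      t[sel] <- t_new
      active[sel[conv]] <- FALSE
    }
  }
  # final distances
  d_out <- numeric(n)
  for (f in unique(face_idx)) {
    sel <- which(face_idx == f)
    fa <- .face_axes(faces[f, 2])
    xi <- matrix(fa$val, length(sel), 3)
    xi[, fa$free[1]] <- s[sel]
    xi[, fa$free[2]] <- t[sel]
    pos <- evaluate_element(mesh, faces[f, 1], xi)
    if (is.null(dim(pos))) pos <- matrix(pos, 1, 3)
    d_out[sel] <- sqrt(rowSums((query[sel, , drop = FALSE] - pos)^2))
  }
  d_out
}

#' Fitting error between a mesh and a binary mask
#'
#' Euclidean distance (mm) from the isosurface vertices of the mask to the
#' closest point of the mesh external surface. Closest points are seeded by
#' nearest neighbour on a subdivided surface and refined by damped Newton
#' iteration in the face parameters (fallback to the seed if refinement
#' diverges). Reports the vertex mean/max (headline numbers) and a
#' surface-Gauss-quadrature-weighted mean (distance from surface Gauss
#' points to the isosurface), the two readings of the surface-integrated
#' error.
#'
#' @param mesh a [hermite_mesh()] with surface faces.
#' @param mask a [binary_mask()].
#' @param sub seed-surface subdivision per face.
#' @param max_vertices optional cap on isosurface vertices (deterministic
#'   regular subsample) to bound runtime.
#' @return list: `mean`, `max`, `weighted_mean`, `per_vertex`, `n_vertices`.
#' @export
fitting_error <- function(mesh, mask, sub = 8L, max_vertices = 20000L) {
  iso <- isosurface_vertices(mask)
  if (nrow(iso) > max_vertices) {
    keep <- seq(1L, nrow(iso), length.out = max_vertices)
    iso <- iso[unique(as.integer(keep)), , drop = FALSE]
  }
  ss <- .surface_samples(mesh, sub = sub)
  nn <- .c_nn_bruteforce(iso, ss$points)
  seed_d <- sqrt(nn$d2)
  face_idx <- ss$face_of[nn$idx]
  st <- ss$st[nn$idx, , drop = FALSE]
  newton_d <- .closest_point_newton(mesh, ss$faces, iso, face_idx, st)
  d <- pmin(seed_d, newton_d)   # Newton can only improve; guard divergence
  # reverse reading: surface Gauss points to nearest isosurface vertex
  sq <- external_surface_points(mesh, names(mesh$surface_faces), order = 4L)
  nn2 <- .c_nn_bruteforce(sq$points, iso)
  wmean <- sum(sq$weights * sqrt(nn2$d2)) / sum(sq$weights)
  list(mean = mean(d), max = max(d), weighted_mean = wmean,
       per_vertex = d, n_vertices = nrow(iso))
}

#' Success criterion for a personalized mesh
#'
#' Success requires a mean fitting error strictly smaller than the voxel
#' diagonal of the target image and a mesh quality (mean Jacobian ratio) at
#' or above the empirical 0.33 threshold.
#'
#' @param report a quality report from [quality_report()] (or any list with
#'   `fitting_error_mean` and `mesh_quality_mean`).
#' @param mask the target [binary_mask()] (supplies the voxel diagonal).
#' @param quality_threshold empirical quality threshold (default 0.33).
#' @return logical flag.
#' @export
success <- function(report, mask, quality_threshold = 0.33) {
  diag_mm <- sqrt(sum(mask$spacing^2))
  isTRUE(report$fitting_error_mean < diag_mm) &&
    isTRUE(report$mesh_quality_mean >= quality_threshold)
}

#' Assemble a quality report
#'
#' @param mesh fitted [hermite_mesh()].
#' @param mask target [binary_mask()].
#' @param quad_order Gauss points per axis for quality.
#' @param quality_threshold success threshold on mean Jacobian ratio.
#' @return list of class `quality_report` with per-element quality,
#'   aggregates, fitting-error statistics, thresholds and the success flag.
#' @export
quality_report <- function(mesh, mask, quad_order = 4L,
                           quality_threshold = 0.33) {
  mq <- mesh_quality(mesh, quad_order)
  fe <- fitting_error(mesh, mask)
  rep <- list(
    per_element_q = mq$per_element,
    mesh_quality_min = mq$min,
    mesh_quality_mean = mq$mean,
    fitting_error_mean = fe$mean,
    fitting_error_max = fe$max,
    fitting_error_weighted = fe$weighted_mean,
    n_isosurface_vertices = fe$n_vertices,
    thresholds = list(quality = quality_threshold,
                      error = sqrt(sum(mask$spacing^2)))
  )
  rep$success <- success(rep, mask, quality_threshold)
  class(rep) <- "quality_report"
  rep
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(paste0("quality_report: error mean %.3f mm (max %.3f), ",
                     "quality mean %.3f (min %.3f), success: %s\n"),
              x$fitting_error_mean, x$fitting_error_max,
              x$mesh_quality_mean, x$mesh_quality_min, x$success))
  invisible(x)
}

#' Transmural linearization (quality enhancement)
#'
#' Resets the radial (xi3-direction) derivative DOFs of every transmural
#' node column to the straight chord between the opposite wall nodes
#' (scaled by the element span), and the xi3-mixed derivatives to the
#' corresponding chord differences of the in-surface derivatives. DOFs not
#' involving xi3 are untouched, so the endocardial and epicardial surfaces
#' are exactly preserved while interior material lines straighten, which
#' raises element regularity.
#'
#' @param mesh a [hermite_mesh()] with `transmural_columns` (set by the
#'   template synthesis; structured meshes only).
#' @return the enhanced [hermite_mesh()].
#' @export
linearize_transmural <- function(mesh) {
  cols <- mesh$transmural_columns
  if (is.null(cols))
    stop("mesh has no transmural column structure (ambiguous pairing)")
  dofs <- mesh$dofs
  for (col in cols) {
    nrr <- length(col) - 1L          # radial element count of this column
    endo <- col[1]; epi <- col[nrr + 1L]
    chord <- dofs[epi, 1, ] - dofs[endo, 1, ]
    clen2 <- sum(chord^2)
    if (clen2 < 1e-24) next          # collapsed column (insertion line)
    u <- chord / sqrt(clen2)
    d13 <- (dofs[epi, 2, ] - dofs[endo, 2, ]) / nrr
    d23 <- (dofs[epi, 3, ] - dofs[endo, 3, ]) / nrr
    d123 <- (dofs[epi, 5, ] - dofs[endo, 5, ]) / nrr
    for (nd in col) {
      # point along the chord, preserving the node's transmural speed;
      # mixed derivatives follow by the chain rule (chord differences of
      # the in-surface derivatives, scaled by the relative speed)
      s <- sum(dofs[nd, 4, ] * u)
      if (s <= 0) s <- sqrt(clen2) / nrr   # degenerate: uniform speed
      rel <- s * nrr / sqrt(clen2)
      dofs[nd, 4, ] <- s * u
      dofs[nd, 6, ] <- rel * d13
      dofs[nd, 7, ] <- rel * d23
      dofs[nd, 8, ] <- rel * d123
    }
  }
  mesh$dofs <- dofs
  mesh
}
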