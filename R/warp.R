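# Variational mesh warping: L2 projection of a dense displacement field
# onto the mesh's Hermite degrees of freedom. The whole continuum is
# warped: nodal DOF increments minimize the volume-weighted L2 norm of the
# difference between the interpolated displacement and the registration
# field at the element Gauss points, per coordinate, via sparse normal
# equations. Position DOFs of tied nodes (collapsed apex rings, RV
# insertion) share one unknown, so tied nodes stay coincident.

# map (node, dof) -> compressed global column index honouring tie groups
.dof_columns <- function(mesh) {
  nn <- dim(mesh$dofs)[1]
  raw <- matrix(seq_len(nn * 8L), nn, 8L)   # row = node, col = dof
  for (g in mesh$tie_groups) {
    if (length(g) < 2L) next
    raw[g, 1L] <- raw[g[1], 1L]             # shared position unknown
  }
  cols <- match(raw, sort(unique(as.vector(raw))))
  matrix(cols, nn, 8L)
}

#' Project a displacement field onto the mesh degrees of freedom
#'
#' Solves, per coordinate, the weighted linear least-squares problem
#' min_delta sum_e sum_g w_g |B(xi_g) delta - u(x_g)|^2 + eps ||delta||^2
#' with Gauss weights w_g including the volume differential det J, and
#' updates the mesh DOFs by the minimizer. Affine fields are reproduced
#' exactly (up to solver tolerance) because the Hermite basis contains
#' affine functions.
#'
#' @param mesh a [hermite_mesh()].
#' @param field a `displacement_field` from [register()], or a function
#'   `(n x 3 points) -> n x 3 displacements` (mm).
#' @param quad_order Gauss points per axis (>= 3 for cubic integrands).
#' @param eps Tikhonov regularization, scaled per column by the normal-matrix
#'   diagonal; stabilizes DOFs with little quadrature support (apex
#'   mixed derivatives).
#' @return the warped [hermite_mesh()] with attribute `"l2_residual"` (mm,
#'   weighted RMS over Gauss points).
#' @export
project_displacement <- function(mesh, field, quad_order = 4L,
                                 eps = 1e-13) {
  if (quad_order < 3L) stop("quad_order must be >= 3")
  q <- .gauss_cube(quad_order)
  ne <- nrow(mesh$elements)
  npq <- nrow(q$xi)
  B0 <- .hermite_basis_3d(q$xi)             # same for every element
  cols_map <- .dof_columns(mesh)
  ncol_tot <- max(cols_map)
  ii <- jj <- vv <- vector("list", ne)
  rhs_pts <- matrix(0, ne * npq, 3)
  wts <- numeric(ne * npq)
  for (e in seq_len(ne)) {
    jac <- element_jacobian(mesh, e, q$xi)
    w <- q$w * pmax(jac$det, 0)
    x <- B0 %*% .elem_dofs(mesh, e)
    rows <- (e - 1L) * npq + seq_len(npq)
    wts[rows] <- w
    rhs_pts[rows, ] <- x
    nodes <- mesh$elements[e, ]
    colset <- as.vector(t(cols_map[nodes, , drop = FALSE]))  # 64, basis order
    ii[[e]] <- rep(rows, times = 64L)
    jj[[e]] <- rep(colset, each = npq)
    vv[[e]] <- as.vector(B0)
  }
  u <- if (is.function(field)) field(rhs_pts) else field_at(field, rhs_pts)
  sw <- sqrt(wts)
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                            x = unlist(vv) * sw[unlist(ii)],
                            dims = c(ne * npq, ncol_tot))
  M0 <- Matrix::crossprod(A)
  dg <- Matrix::diag(M0)
  rhs <- Matrix::crossprod(A, u * sw)
  # relative ridge: shrinks every increment by ~eps regardless of the
  # (widely varying) quadrature support of each DOF; the floor keeps
  # zero-support columns (apex mixed derivatives) non-singular, and is
  # raised only if the factorization actually fails
  delta <- NULL
  for (floor_rel in c(1e-12, 1e-6, 1e-2)) {
    ridge <- eps * pmax(dg, floor_rel * mean(dg)) +
      .Machine$double.xmin
    M <- M0 + Matrix::Diagonal(ncol_tot, ridge)
    delta <- tryCatch(as.matrix(Matrix::solve(M, rhs)),
                      error = function(e) NULL)
    if (!is.null(delta) && all(is.finite(delta))) break
    delta <- NULL
  }
  if (is.null(delta))
    stop("singular projection system (nullspace in the DOF support)")
  # scatter back: every (node, dof) reads its (possibly shared) column
  dofs <- mesh$dofs
  nn <- dim(dofs)[1]
  for (d in 1:8) {
    dofs[, d, ] <- dofs[, d, ] + delta[cols_map[, d], , drop = FALSE]
  }
  out <- mesh
  out$dofs <- dofs
  # weighted RMS residual of the projection
  resid <- .l2_resid_points(mesh, out, u, wts, npq, B0)
  attr(out, "l2_residual") <- resid
  out
}

.l2_resid_points <- function(before, after, u, wts, npq, B0) {
  ne <- nrow(before$elements)
  acc <- 0
  for (e in seq_len(ne)) {
    rows <- (e - 1L) * npq + seq_len(npq)
    disp <- B0 %*% (.elem_dofs(after, e) - .elem_dofs(before, e))
    acc <- acc + sum(wts[rows] * rowSums((disp - u[rows, ])^2))
  }
  sqrt(acc / max(sum(wts), 1e-300))
}

#' Weighted RMS projection residual
#'
#' Root-mean-square (volume-weighted over element Gauss points) of the
#' difference between the mesh displacement `mesh_after - mesh_before` and
#' the field, i.e. the L2 norm of the projection error per unit volume.
#'
#' @param mesh_before,mesh_after meshes sharing topology.
#' @param field displacement field or function as in
#'   [project_displacement()].
#' @param quad_order Gauss points per axis.
#' @return scalar (mm).
#' @export
l2_residual <- function(mesh_before, mesh_after, field, quad_order = 4L) {
  q <- .gauss_cube(quad_order)
  npq <- nrow(q$xi)
  B0 <- .hermite_basis_3d(q$xi)
  ne <- nrow(mesh_before$elements)
  wts <- numeric(ne * npq)
  pts <- matrix(0, ne * npq, 3)
  for (e in seq_len(ne)) {
    jac <- element_jacobian(mesh_before, e, q$xi)
    rows <- (e - 1L) * npq + seq_len(npq)
    wts[rows] <- q$w * pmax(jac$det, 0)
    pts[rows, ] <- B0 %*% .elem_dofs(mesh_before, e)
  }
  u <- if (is.function(field)) field(pts) else field_at(field, pts)
  .l2_resid_points(mesh_before, mesh_after, u, wts, npq, B0)
}
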