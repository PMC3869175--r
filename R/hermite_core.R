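#' @useDynLib ventmesh, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal DOF ordering per node (per coordinate):
#   1 value, 2 d/dxi1, 3 d/dxi2, 4 d/dxi3,
#   5 d2/dxi1dxi2, 6 d2/dxi1dxi3, 7 d2/dxi2dxi3, 8 d3/dxi1dxi2dxi3
# Derivative flags per DOF along each local axis:
.DOF_DA <- c(0L, 1L, 0L, 0L, 1L, 1L, 0L, 1L)
.DOF_DB <- c(0L, 0L, 1L, 0L, 1L, 0L, 1L, 1L)
.DOF_DC <- c(0L, 0L, 0L, 1L, 0L, 1L, 1L, 1L)
# Corner ordering: corner index = 1 + i1 + 2*i2 + 4*i3 with i_k in {0,1}
.CORNER_I1 <- c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L)
.CORNER_I2 <- c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L)
.CORNER_I3 <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)

#' One-dimensional cubic Hermite shape functions
#'
#' Returns the four cubic Hermite shape functions at `xi`: the two value
#' (endpoint-interpolating) functions and the two unit-derivative functions,
#' in the order (value-at-0, value-at-1, derivative-at-0, derivative-at-1).
#' These are the standard C1 interpolation polynomials
#' \eqn{1-3\xi^2+2\xi^3}, \eqn{3\xi^2-2\xi^3}, \eqn{\xi(\xi-1)^2},
#' \eqn{\xi^2(\xi-1)}.
#'
#' @param xi evaluation coordinate(s) in \[0, 1\].
#' @return numeric matrix with `length(xi)` rows and 4 columns.
#' @export
#' @examples
#' hermite_basis_1d(0.5)
hermite_basis_1d <- function(xi) {
  if (any(!is.finite(xi)) || any(xi < 0 | xi > 1))
    stop("xi must lie in [0, 1]")
  cbind(
    h00 = 1 - 3 * xi^2 + 2 * xi^3,
    h01 = 3 * xi^2 - 2 * xi^3,
    h10 = xi * (xi - 1)^2,
    h11 = xi^2 * (xi - 1)
  )
}

# m-th derivative of the 1D shape function of given type (0 value / 1 slope)
# anchored at the given end (0/1). Vectorized over xi.
.sh1 <- function(xi, type, end, m = 0L) {
  if (type == 0L) {
    if (end == 0L) {
      switch(m + 1L, 1 - 3 * xi^2 + 2 * xi^3, -6 * xi + 6 * xi^2, -6 + 12 * xi)
    } else {
      switch(m + 1L, 3 * xi^2 - 2 * xi^3, 6 * xi - 6 * xi^2, 6 - 12 * xi)
    }
  } else {
    if (end == 0L) {
      switch(m + 1L, xi - 2 * xi^2 + xi^3, 1 - 4 * xi + 3 * xi^2, -4 + 6 * xi)
    } else {
      switch(m + 1L, xi^3 - xi^2, 3 * xi^2 - 2 * xi, 6 * xi - 2)
    }
  }
}

# Tensor-product tricubic Hermite basis matrix: n x 64, columns ordered
# (corner-1)*8 + dof. `deriv` gives the differentiation order per local axis.
.hermite_basis_3d <- function(xi, deriv = c(0L, 0L, 0L)) {
  xi <- matrix(xi, ncol = 3)
  n <- nrow(xi)
  # per-axis 1D tables: list[[axis]][[type+1]][[end+1]] -> numeric(n)
  tab <- lapply(1:3, function(ax) {
    lapply(0:1, function(type) lapply(0:1, function(end)
      .sh1(xi[, ax], type, end, deriv[ax])))
  })
  B <- matrix(0, n, 64L)
  for (cn in 1:8) {
    i1 <- .CORNER_I1[cn]; i2 <- .CORNER_I2[cn]; i3 <- .CORNER_I3[cn]
    for (d in 1:8) {
      B[, (cn - 1L) * 8L + d] <-
        tab[[1]][[.DOF_DA[d] + 1L]][[i1 + 1L]] *
        tab[[2]][[.DOF_DB[d] + 1L]][[i2 + 1L]] *
        tab[[3]][[.DOF_DC[d] + 1L]][[i3 + 1L]]
    }
  }
  B
}

# Gather element DOFs into a 64 x 3 matrix in basis-column order.
.elem_dofs <- function(mesh, element_id) {
  nodes <- mesh$elements[element_id, ]
  D <- matrix(0, 64L, 3L)
  for (cn in 1:8)
    D[(cn - 1L) * 8L + 1:8, ] <- mesh$dofs[nodes[cn], , ]
  D
}

#' Construct a tricubic Hermite mesh object
#'
#' Low-level constructor; users normally obtain meshes from
#' [synthesize_lv()]/[synthesize_biv()] or [read_ex()].
#'
#' @param dofs numeric array `(n_nodes, 8, 3)`: per node, the 8 Hermite DOF
#'   vectors (value, three first derivatives, three mixed seconds, mixed
#'   third) for each coordinate, with derivatives taken with respect to unit
#'   element-local coordinates.
#' @param elements integer matrix `n_elem x 8` of node ids in tensor-product
#'   corner order (xi1 fastest, then xi2, then xi3).
#' @param topology `"LV"` or `"BiV"`.
#' @param resolution named integer vector `(radial, circ, long)`.
#' @param apex_style `"collapsed"`, `"hole"` or `"patch"`.
#' @param surface_faces named list of 2-column matrices `(element, face)`
#'   labelling external faces; face codes 1..6 are xi1=0, xi1=1, xi2=0,
#'   xi2=1, xi3=0, xi3=1.
#' @param tie_groups list of integer vectors of nodes constrained to a
#'   common position (collapsed apex rings, RV insertion line).
#' @param regions optional character vector of per-element region labels.
#' @return an object of class `hermite_mesh`.
#' @export
hermite_mesh <- function(dofs, elements, topology = "LV",
                         resolution = c(radial = 1L, circ = 4L, long = 2L),
                         apex_style = "collapsed",
                         surface_faces = list(), tie_groups = list(),
                         regions = NULL) {
  stopifnot(length(dim(dofs)) == 3L, dim(dofs)[2] == 8L, dim(dofs)[3] == 3L)
  if (is.null(dim(elements))) elements <- matrix(elements, nrow = 1L)
  if (ncol(elements) != 8L) stop("elements must have ncol = 8")
  elements <- matrix(as.integer(elements), ncol = 8L)
  if (any(elements < 1L) || any(elements > dim(dofs)[1]))
    stop("element node id out of range")
  if (!all(is.finite(dofs))) stop("non-finite DOF")
  m <- structure(list(
    dofs = dofs, elements = elements, topology = topology,
    resolution = resolution, apex_style = apex_style,
    surface_faces = surface_faces, tie_groups = tie_groups,
    regions = regions
  ), class = "hermite_mesh")
  m
}

#' @export
print.hermite_mesh <- function(x, ...) {
  cat(sprintf("hermite_mesh: %s, %d nodes, %d elements (%s apex)\n",
              x$topology, dim(x$dofs)[1], nrow(x$elements), x$apex_style))
  cat(sprintf("  resolution (radial, circ, long): %s\n",
              paste(x$resolution, collapse = ", ")))
  if (length(x$surface_faces))
    cat("  surface faces:",
        paste(sprintf("%s(%d)", names(x$surface_faces),
                      vapply(x$surface_faces, nrow, 1L)), collapse = ", "),
        "\n")
  invisible(x)
}

.check_element_id <- function(mesh, element_id) {
  if (length(element_id) != 1L || element_id < 1L ||
      element_id > nrow(mesh$elements))
    stop("invalid element id")
}

#' Evaluate the geometry of one element
#'
#' Tensor-product tricubic Hermite interpolation of the element's 8 nodes
#' (8 DOF vectors each) at local coordinates `xi`.
#'
#' @param mesh a [hermite_mesh()].
#' @param element_id element index.
#' @param xi numeric vector of length 3, or an `n x 3` matrix, in \[0,1\]^3.
#' @return position(s) in mm: numeric length-3 vector or `n x 3` matrix.
#' @export
evaluate_element <- function(mesh, element_id, xi) {
  .check_element_id(mesh, element_id)
  single <- is.null(dim(xi))
  xi <- matrix(xi, ncol = 3)
  if (any(xi < -1e-12 | xi > 1 + 1e-12)) stop("xi outside [0,1]^3")
  B <- .hermite_basis_3d(xi)
  out <- B %*% .elem_dofs(mesh, element_id)
  if (single) drop(out) else out
}

#' Analytic element Jacobian
#'
#' The 3x3 matrix of partial derivatives of the interpolated position with
#' respect to the local coordinates, obtained by differentiating the Hermite
#' basis (no finite differencing), together with its determinant (the volume
#' differential, mm^3 per unit local volume).
#'
#' @inheritParams evaluate_element
#' @return for a single `xi`: `list(J = 3x3 matrix, det = scalar)`; for a
#'   matrix of points: `list(J = n x 3 x 3 array, det = numeric(n))`.
#' @export
element_jacobian <- function(mesh, element_id, xi) {
  .check_element_id(mesh, element_id)
  single <- is.null(dim(xi))
  xi <- matrix(xi, ncol = 3)
  D <- .elem_dofs(mesh, element_id)
  n <- nrow(xi)
  J <- array(0, c(n, 3, 3))  # J[, i, k] = d x_i / d xi_k
  for (k in 1:3) {
    dv <- c(0L, 0L, 0L); dv[k] <- 1L
    J[, , k] <- .hermite_basis_3d(xi, dv) %*% D
  }
  detJ <- J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
          J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
          J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
  if (single) list(J = matrix(J[1, , ], 3, 3), det = detJ[1])
  else list(J = J, det = detJ)
}

#' Gauss-Legendre nodes and weights on \[0, 1\]
#'
#' Computed by the Golub-Welsch eigenvalue method; deterministic.
#'
#' @param n quadrature order (number of points).
#' @return list with `nodes` and `weights`, both `numeric(n)`.
#' @export
gauss_legendre <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0.5, weights = 1))
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  Tm <- diag(0, n)
  Tm[cbind(k, k + 1)] <- beta
  Tm[cbind(k + 1, k)] <- beta
  e <- eigen(Tm, symmetric = TRUE)
  ord <- order(e$values)
  x <- e$values[ord]
  w <- 2 * (e$vectors[1, ord])^2
  list(nodes = (x + 1) / 2, weights = w / 2)
}

# Tensor-product Gauss grid on the unit cube: matrix of points + weights.
.gauss_cube <- function(order) {
  g <- gauss_legendre(order)
  idx <- expand.grid(a = seq_len(order), b = seq_len(order),
                     c = seq_len(order))
  list(
    xi = cbind(g$nodes[idx$a], g$nodes[idx$b], g$nodes[idx$c]),
    w = g$weights[idx$a] * g$weights[idx$b] * g$weights[idx$c]
  )
}

#' Mesh volume by Gauss quadrature
#'
#' Sum over elements of the integral of det J with a tensor-product
#' Gauss-Legendre rule. Gauss points are strictly interior, so collapsed-apex
#' elements (singular on the collapsed face only) integrate cleanly.
#'
#' @param mesh a [hermite_mesh()].
#' @param quad_order Gauss points per axis (default 4).
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh, quad_order = 4L) {
  q <- .gauss_cube(quad_order)
  total <- 0
  for (e in seq_len(nrow(mesh$elements))) {
    total <- total + sum(q$w * element_jacobian(mesh, e, q$xi)$det)
  }
  total
}

# face code -> fixed axis, fixed value, free axes (increasing)
.face_axes <- function(face) {
  axis <- (face + 1L) %/% 2L
  val <- (face + 1L) %% 2L  # face 1 -> 0, face 2 -> 1, ...
  free <- setdiff(1:3, axis)
  list(axis = axis, val = val, free = free)
}

#' Gauss points and area weights on labelled surface faces
#'
#' Samples the selected bicubic boundary patches at tensor-product Gauss
#' points; the weight of each point is the local surface area element times
#' the Gauss weights, so the weights of a face sum to its area.
#'
#' @param mesh a [hermite_mesh()].
#' @param face_set character vector of labels from `mesh$surface_faces`, or a
#'   2-column matrix `(element, face)`.
#' @param order Gauss points per face axis.
#' @return list with `points` (n x 3 mm), `weights` (mm^2), `element`,
#'   `face`, and the face-local coordinates `st` (n x 2).
#' @export
external_surface_points <- function(mesh, face_set, order = 4L) {
  faces <- if (is.character(face_set)) {
    if (!length(face_set)) stop("empty face set")
    missing <- setdiff(face_set, names(mesh$surface_faces))
    if (length(missing)) stop("unknown face label: ", missing[1])
    do.call(rbind, mesh$surface_faces[face_set])
  } else face_set
  if (is.null(faces) || nrow(faces) == 0L) stop("empty face set")
  g <- gauss_legendre(order)
  st <- as.matrix(expand.grid(s = g$nodes, t = g$nodes))
  wg <- expand.grid(ws = g$weights, wt = g$weights)
  wst <- wg$ws * wg$wt
  npts <- nrow(st)
  nf <- nrow(faces)
  pts <- matrix(0, nf * npts, 3)
  wts <- numeric(nf * npts)
  for (f in seq_len(nf)) {
    fa <- .face_axes(faces[f, 2])
    xi <- matrix(fa$val, npts, 3)
    xi[, fa$free[1]] <- st[, 1]
    xi[, fa$free[2]] <- st[, 2]
    jac <- element_jacobian(mesh, faces[f, 1], xi)
    t1 <- jac$J[, , fa$free[1], drop = FALSE]
    t2 <- jac$J[, , fa$free[2], drop = FALSE]
    cr <- cbind(t1[, 2, 1] * t2[, 3, 1] - t1[, 3, 1] * t2[, 2, 1],
                t1[, 3, 1] * t2[, 1, 1] - t1[, 1, 1] * t2[, 3, 1],
                t1[, 1, 1] * t2[, 2, 1] - t1[, 2, 1] * t2[, 1, 1])
    rows <- (f - 1L) * npts + seq_len(npts)
    pts[rows, ] <- .hermite_basis_3d(xi) %*% .elem_dofs(mesh, faces[f, 1])
    wts[rows] <- sqrt(rowSums(cr^2)) * wst
  }
  list(points = pts, weights = wts,
       element = rep(faces[, 1], each = npts),
       face = rep(faces[, 2], each = npts),
       st = st[rep(seq_len(npts), times = nf), , drop = FALSE])
}

#' Convert to a cubic Lagrange mesh
#'
#' Samples each element's Hermite interpolant on the 4 x 4 x 4 tensor grid
#' xi in \{0, 1/3, 2/3, 1\}^3; nodes shared between elements are merged by
#' position (1e-8 mm tolerance key), so continuity of the Hermite mesh
#' carries over node-exactly.
#'
#' @param mesh a [hermite_mesh()].
#' @return list of class `lagrange_mesh`: `nodes` (global positions),
#'   `elem_nodes` (`n_elem x 64` node ids, xi1 fastest), and `xi_grid`.
#' @export
convert_to_lagrange <- function(mesh) {
  ticks <- c(0, 1, 2, 3) / 3
  grid <- as.matrix(expand.grid(x1 = ticks, x2 = ticks, x3 = ticks))
  ne <- nrow(mesh$elements)
  allpts <- vector("list", ne)
  for (e in seq_len(ne)) allpts[[e]] <- evaluate_element(mesh, e, grid)
  P <- do.call(rbind, allpts)
  key <- apply(round(P, 8), 1, paste, collapse = "/")
  ids <- match(key, unique(key))
  nodes <- P[!duplicated(key), , drop = FALSE]
  structure(list(
    nodes = nodes,
    elem_nodes = matrix(ids, nrow = ne, byrow = TRUE),
    xi_grid = grid
  ), class = "lagrange_mesh")
}
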