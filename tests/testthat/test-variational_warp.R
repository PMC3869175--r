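# Variational L2 projection of displacement fields onto mesh DOFs.

test_that("zero field leaves the mesh unchanged", {
  m <- small_lv()
  out <- project_displacement(m, function(p) matrix(0, nrow(p), 3))
  expect_lt(max(abs(out$dofs - m$dofs)), 1e-10)
  expect_lt(attr(out, "l2_residual"), 1e-10)
})

test_that("affine fields are reproduced exactly", {
  m <- small_lv()
  A <- matrix(c(1.1, 0.05, 0, -0.02, 0.95, 0.04, 0.01, 0, 1.05), 3, 3)
  b <- c(2, -1, 0.5)
  field <- function(p) sweep(p %*% t(A - diag(3)), 2, b, `+`)
  out <- project_displacement(m, field)
  want <- affine_mesh(m, A, b)
  expect_lt(max(abs(out$dofs - want$dofs)), 1e-8)
  expect_lt(l2_residual(m, out, field), 1e-8)
})

test_that("L2 residual decreases under circumferential refinement", {
  # smooth harmonic field Im((x+iy)^3): varies with the third angular
  # harmonic, so the approximation error is governed by the
  # circumferential resolution being refined (and stays smooth at the
  # apex axis, unlike a raw function of the polar angle)
  field <- function(p) cbind(0, 0, (3 * p[, 1]^2 * p[, 2] - p[, 2]^3) /
                                     5000)
  res <- vapply(c(6, 12, 24), function(ncirc) {
    spec <- template_spec("LV", resolution = c(1, ncirc, 4),
                          lv_outer_radii = c(26, 25, 40),
                          lv_wall_thickness = 8)
    m <- synthesize_lv(spec)
    out <- project_displacement(m, field)
    l2_residual(m, out, field)
  }, 0)
  expect_true(all(diff(res) < 0))
})

test_that("projection beats any nodal-interpolation warp in the L2 norm", {
  m <- small_lv()
  fields <- list(
    function(p) cbind(0.8 * sin(p[, 3] / 10), 0 * p[, 1], 0 * p[, 1]),
    function(p) cbind(0 * p[, 1], 0.5 * cos(p[, 1] / 8), 0 * p[, 1]),
    function(p) 0.02 * p,
    function(p) cbind(0.3 * p[, 2] / 10, 0.6 * sin(p[, 3] / 15),
                      0.4 * cos(p[, 2] / 12)),
    function(p) cbind(0.5 * exp(-((p[, 3] + 30) / 20)^2), 0 * p[, 1],
                      0 * p[, 1])
  )
  for (field in fields) {
    proj <- project_displacement(m, field)
    # nodal-warp oracle: displace only nodal positions by the field value
    nodal <- m
    nodal$dofs[, 1, ] <- nodal$dofs[, 1, ] + field(m$dofs[, 1, ])
    expect_lte(l2_residual(m, proj, field),
               l2_residual(m, nodal, field) + 1e-12)
  }
})

test_that("first-order optimality: single-DOF perturbations never help", {
  m <- small_lv()
  field <- function(p) cbind(0.6 * sin(p[, 3] / 12),
                             0.3 * cos(p[, 1] / 9), 0 * p[, 1])
  proj <- project_displacement(m, field)
  q <- ventmesh:::.gauss_cube(4L)
  B0 <- ventmesh:::.hermite_basis_3d(q$xi)
  npq <- nrow(q$xi)
  objective <- function(mesh) {
    acc <- 0
    for (e in seq_len(nrow(mesh$elements))) {
      jac <- element_jacobian(m, e, q$xi)
      w <- q$w * pmax(jac$det, 0)
      disp <- B0 %*% (ventmesh:::.elem_dofs(mesh, e) -
                        ventmesh:::.elem_dofs(m, e))
      x <- B0 %*% ventmesh:::.elem_dofs(m, e)
      acc <- acc + sum(w * rowSums((disp - field(x))^2))
    }
    acc
  }
  f0 <- objective(proj)
  set.seed(11)
  for (i in 1:8) {
    nd <- sample(dim(m$dofs)[1], 1)
    dof <- sample(8, 1)
    coord <- sample(3, 1)
    for (s in c(-1e-3, 1e-3)) {
      pert <- proj
      pert$dofs[nd, dof, coord] <- pert$dofs[nd, dof, coord] + s
      # tied position DOFs must be perturbed jointly to stay admissible
      if (dof == 1L) {
        for (g in m$tie_groups) if (nd %in% g) {
          others <- setdiff(g, nd)
          pert$dofs[others, 1, coord] <- pert$dofs[others, 1, coord] + s
        }
      }
      expect_gte(objective(pert), f0 - 1e-9)
    }
  }
})

test_that("Galerkin orthogonality of the projection residual", {
  spec <- template_spec("LV", resolution = c(1, 6, 3),
                        lv_outer_radii = c(26, 25, 40),
                        lv_wall_thickness = 8)
  m <- synthesize_lv(spec)
  field <- function(p) cbind(0.8 * sin(p[, 3] / 10), 0 * p[, 1],
                             0.2 * p[, 2] / 10)
  proj <- project_displacement(m, field, eps = 0)
  q <- ventmesh:::.gauss_cube(4L)
  B0 <- ventmesh:::.hermite_basis_3d(q$xi)
  cols_map <- ventmesh:::.dof_columns(m)
  ncols <- max(cols_map)
  inner <- numeric(ncols)
  scale <- numeric(ncols)
  for (e in seq_len(nrow(m$elements))) {
    jac <- element_jacobian(m, e, q$xi)
    w <- q$w * pmax(jac$det, 0)
    x <- B0 %*% ventmesh:::.elem_dofs(m, e)
    resid <- (B0 %*% (ventmesh:::.elem_dofs(proj, e) -
                        ventmesh:::.elem_dofs(m, e)) - field(x))[, 1]
    nodes <- m$elements[e, ]
    colset <- as.vector(t(cols_map[nodes, , drop = FALSE]))
    for (c64 in 1:64) {
      j <- colset[c64]
      inner[j] <- inner[j] + sum(w * B0[, c64] * resid)
      scale[j] <- scale[j] + sum(w * B0[, c64]^2)
    }
  }
  rel <- abs(inner) / (sqrt(scale) * sqrt(sum(scale)) + 1e-30)
  expect_lt(max(rel), 1e-6)
})

test_that("quadrature order below 3 is rejected", {
  expect_error(project_displacement(small_lv(),
                                    function(p) matrix(0, nrow(p), 3),
                                    quad_order = 2L), ">= 3")
})
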