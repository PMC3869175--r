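# Quality metrics, fitting error, success criterion, transmural
# linearization.

test_that("Jacobian ratio: affine elements, dense-grid oracle, inversions", {
  expect_equal(jacobian_ratio(make_affine_element(), 1), 1)
  A <- matrix(c(2, 0.3, 0, 0, 1.5, 0.1, 0.2, 0, 0.8), 3, 3)
  expect_equal(jacobian_ratio(make_affine_element(A), 1), 1)
  # curved element: x -> (xi1, xi2, xi3 (1 + xi1)); det J = 1 + xi1
  dofs <- array(0, c(8, 8, 3))
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  for (n in 1:8) {
    x <- corners[n, ]
    dofs[n, 1, ] <- c(x[1], x[2], x[3] * (1 + x[1]))
    dofs[n, 2, ] <- c(1, 0, x[3])       # d/dxi1
    dofs[n, 3, ] <- c(0, 1, 0)          # d/dxi2
    dofs[n, 4, ] <- c(0, 0, 1 + x[1])   # d/dxi3
    dofs[n, 6, ] <- c(0, 0, 1)          # d2/dxi1 dxi3
  }
  mc <- hermite_mesh(dofs, matrix(1:8, 1, 8))
  # order 6 keeps the extreme Gauss nodes close to the dense-grid margin,
  # so quadrature and grid sample comparable interiors
  got <- jacobian_ratio(mc, 1, quad_order = 6L)
  g <- seq(0.5 / 20, 1 - 0.5 / 20, length.out = 20)
  gr <- as.matrix(expand.grid(g, g, g))
  dj <- element_jacobian(mc, 1, gr)$det
  expect_lt(abs(got - min(dj) / max(dj)) / (min(dj) / max(dj)), 0.05)
  # inverted element reports quality 0 with a flag
  bad <- make_affine_element(diag(c(-1, 1, 1)))
  qb <- jacobian_ratio(bad, 1)
  expect_equal(as.numeric(qb), 0)
  expect_true(attr(qb, "inverted"))
})

test_that("degrading an element by pulling a node decreases Q monotonically", {
  qs <- vapply(c(0, 0.2, 0.4, 0.6), function(pull) {
    m <- make_affine_element()
    m$dofs[8, 1, ] <- m$dofs[8, 1, ] + pull
    jacobian_ratio(m, 1)
  }, 0)
  expect_true(all(diff(qs) < 0))
})

test_that("mesh quality aggregates and rigid invariance", {
  m <- small_lv()
  q <- mesh_quality(m)
  expect_true(all(q$per_element > 0 & q$per_element <= 1))
  expect_lte(q$min, q$mean)
  qr <- mesh_quality(affine_mesh(m, rot3(c(1, 0, 1), 1.1), c(10, 0, -5)))
  expect_equal(qr$per_element, q$per_element, tolerance = 1e-8)
})

test_that("fitting error: self-consistency, translation, zero on surface", {
  m <- small_lv()
  grid <- list(dims = c(60L, 60L, 70L), spacing = c(1, 1, 1),
               origin = c(-30, -30, -45))
  mask <- rasterize_mesh(m, grid)
  fe <- fitting_error(m, mask)
  expect_lt(fe$mean, sqrt(3))          # within the voxel diagonal
  expect_true(all(fe$per_vertex >= 0))
  expect_gt(fe$weighted_mean, 0)
  # translating the mesh 2 mm away: the max error grows by ~2 mm; the
  # mean grows too but stays below 2 mm because the displacement is
  # tangential over much of a closed surface (points slide along it)
  mt <- affine_mesh(m, diag(3), c(2, 0, 0))
  fet <- fitting_error(mt, mask)
  expect_gt(fet$mean, fe$mean + 0.5)
  expect_lt(fet$mean, 2 + fe$mean)
  expect_gte(fet$max, fe$max - 1e-9)
  expect_lt(fet$max, fe$max + 3.5)
  # points sampled exactly on the surface have zero distance
  sp <- external_surface_points(m, "epi", order = 2L)
  ss <- ventmesh:::.surface_samples(m, sub = 8L)
  nn <- ventmesh:::.c_nn_bruteforce(sp$points[1:20, , drop = FALSE],
                                    ss$points)
  d <- ventmesh:::.closest_point_newton(m, ss$faces,
                                        sp$points[1:20, , drop = FALSE],
                                        ss$face_of[nn$idx],
                                        ss$st[nn$idx, , drop = FALSE])
  expect_lt(max(d), 1e-6)
})

test_that("metrics are invariant under joint translation of mesh and mask", {
  m <- small_lv()
  grid <- list(dims = c(40L, 40L, 46L), spacing = c(1.5, 1.5, 1.5),
               origin = c(-30, -30, -45))
  mask <- rasterize_mesh(m, grid)
  t <- c(7.5, -3, 4.5)
  m2 <- affine_mesh(m, diag(3), t)
  mask2 <- binary_mask(mask$voxels, mask$spacing, mask$origin + t)
  f1 <- fitting_error(m, mask)
  f2 <- fitting_error(m2, mask2)
  expect_equal(f1$mean, f2$mean, tolerance = 1e-8)
  expect_equal(f1$max, f2$max, tolerance = 1e-8)
})

test_that("success criterion and its boundary conventions", {
  mk <- binary_mask(array(TRUE, c(2, 2, 2)), spacing = c(1, 1, 1))
  rep_ok <- list(fitting_error_mean = 1.0, mesh_quality_mean = 0.37)
  expect_true(success(rep_ok, mk))        # 1.0 < 1.732, 0.37 >= 0.33
  rep_q <- list(fitting_error_mean = 0.5, mesh_quality_mean = 0.20)
  expect_false(success(rep_q, mk))        # quality below threshold
  rep_edge <- list(fitting_error_mean = sqrt(3),
                   mesh_quality_mean = 0.5)
  expect_false(success(rep_edge, mk))     # error == diagonal: strict
  rep_qedge <- list(fitting_error_mean = 0.5, mesh_quality_mean = 0.33)
  expect_true(success(rep_qedge, mk))     # quality == threshold: inclusive
})

test_that("transmural linearization: idempotence, untouched DOFs, chord", {
  m <- small_lv()
  lin1 <- linearize_transmural(m)
  lin2 <- linearize_transmural(lin1)
  expect_equal(lin2$dofs, lin1$dofs, tolerance = 1e-12)
  # DOFs not involving xi3 are bit-exact
  expect_identical(lin1$dofs[, c(1, 2, 3, 5), ], m$dofs[, c(1, 2, 3, 5), ])
  # surfaces unchanged: endo/epi evaluations identical
  st <- as.matrix(expand.grid(a = c(0.2, 0.7), b = c(0.3, 0.8)))
  for (r in seq_len(nrow(st))) {
    expect_equal(evaluate_element(lin1, 5, c(st[r, 1], st[r, 2], 0)),
                 evaluate_element(m, 5, c(st[r, 1], st[r, 2], 0)),
                 tolerance = 1e-12)
    expect_equal(evaluate_element(lin1, 5, c(st[r, 1], st[r, 2], 1)),
                 evaluate_element(m, 5, c(st[r, 1], st[r, 2], 1)),
                 tolerance = 1e-12)
  }
  # transmural node lines are straight: the mid-parameter point of a node
  # column lies on the chord between its wall-surface endpoints (the
  # parameterization along the chord keeps the nodes' transmural speeds,
  # so it is straight but not necessarily uniform)
  nc <- m$resolution[["circ"]]
  for (colq in c(nc + 2L, 2L * nc + 3L)) {
    col <- lin1$transmural_columns[[colq]]
    p0 <- lin1$dofs[col[1], 1, ]
    p1 <- lin1$dofs[col[length(col)], 1, ]
    u <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
    # evaluate the transmural curve at several interior parameters via
    # the element owning this column
    ic <- (colq - 1L) %% nc + 1L
    jl <- (colq - 1L) %/% nc        # node row index = element row
    e <- ic + nc * (jl - 1L)
    for (x3 in c(0.25, 0.5, 0.75)) {
      p <- evaluate_element(lin1, e, c(0, 1, x3))
      v <- p - p0
      off <- v - sum(v * u) * u
      expect_lt(sqrt(sum(off^2)), 1e-8)
    }
  }
  # error without column structure
  m2 <- m
  m2$transmural_columns <- NULL
  expect_error(linearize_transmural(m2), "ambiguous")
})

test_that("quality report assembles and prints", {
  m <- small_lv()
  grid <- list(dims = c(40L, 40L, 46L), spacing = c(1.5, 1.5, 1.5),
               origin = c(-30, -30, -45))
  mask <- rasterize_mesh(m, grid)
  rep <- quality_report(m, mask)
  expect_s3_class(rep, "quality_report")
  expect_lte(rep$mesh_quality_min, rep$mesh_quality_mean)
  expect_equal(rep$thresholds$error, sqrt(sum(mask$spacing^2)))
  expect_true(is.logical(rep$success))
  expect_output(print(rep), "quality_report")
})

test_that("isosurface vertices are edge midpoints of the binary mask", {
  v <- array(FALSE, c(4, 4, 4))
  v[2, 2, 2] <- TRUE
  mk <- binary_mask(v, spacing = c(2, 2, 2), origin = c(0, 0, 0))
  iso <- isosurface_vertices(mk)
  expect_equal(nrow(iso), 6)            # one crossing per face direction
  ctr <- c(2, 2, 2)                     # world position of the voxel
  d <- sqrt(rowSums(sweep(iso, 2, ctr)^2))
  expect_equal(d, rep(1, 6))            # midpoints at half a voxel
})
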