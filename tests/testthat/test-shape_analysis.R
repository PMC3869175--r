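# Shape analysis: pools, valves, basal plane, axes, dimensions, truncation,
# initial affine.

test_that("LV phantom yields one pool with the analytic cavity centroid", {
  ps <- small_phantom_spec()
  ph <- generate_mask(ps)
  p <- find_pools_and_valves(ph$mask)
  expect_null(p$rv_pool)
  expect_true(any(p$valve_voxels))
  idx <- which(p$lv_pool, arr.ind = TRUE) - 1L
  ctr <- colMeans(sweep(sweep(idx, 2, ph$mask$spacing, `*`), 2,
                        ph$mask$origin, `+`))
  # analytic centroid of the truncated solid inner ellipsoid
  td <- ventmesh:::.template_descriptor(
    template_spec("LV", lv_outer_radii = ps$lv_outer_radii,
                  lv_wall_thickness = ps$wall_thickness,
                  base_height = ps$base_height))
  expect_lt(max(abs(ctr - td$lv_centroid)), max(ps$spacing))
})

test_that("BiV phantom yields two pools with LV the larger cavity", {
  ph <- generate_mask(phantom_spec("BiV", spacing = c(2, 2, 2)))
  p <- find_pools_and_valves(ph$mask)
  expect_false(is.null(p$rv_pool))
  expect_gt(sum(p$lv_pool), sum(p$rv_pool))
})

test_that("solid blob raises a diagnostic; closed shell has no valves", {
  solid <- array(FALSE, c(20, 20, 20))
  solid[5:15, 5:15, 5:15] <- TRUE
  expect_error(find_pools_and_valves(binary_mask(solid)), "solid blob")
  # closed shell (no basal opening): valves empty -> analyze_shape errors
  sh <- array(FALSE, c(24, 24, 24))
  idx <- as.matrix(expand.grid(1:24, 1:24, 1:24)) - 12.5
  r <- sqrt(rowSums(idx^2))
  sh[r < 9 & r > 5.5] <- TRUE
  expect_error(analyze_shape(binary_mask(sh)), "closed shell")
})

test_that("basal plane: flat and tilted truncations recovered", {
  ps <- small_phantom_spec()
  ph <- generate_mask(ps)
  d <- analyze_shape(ph$mask)
  pl <- d$basal_plane
  expect_lt(abs(sum(pl$normal * c(0, 0, 1))) - 1, 1e-6)
  # plane height within half a voxel (+ boundary-midpoint offset)
  expect_lt(abs(sum(pl$point * pl$normal) - ps$base_height),
            1.5 * ps$spacing[3])
  # coplanar synthetic voxels -> exact plane
  vv <- array(FALSE, c(10, 10, 10))
  vv[2:9, 2:9, 5] <- TRUE
  pf <- fit_basal_plane(vv, c(1, 1, 1), c(0, 0, 0))
  expect_equal(abs(pf$normal), c(0, 0, 1), tolerance = 1e-9)
  expect_error(fit_basal_plane(array(FALSE, c(3, 3, 3)), c(1, 1, 1),
                               c(0, 0, 0)), "3 valve voxels")
  # collinear voxels -> degenerate
  ln <- array(FALSE, c(10, 10, 10))
  ln[2:9, 5, 5] <- TRUE
  expect_error(fit_basal_plane(ln, c(1, 1, 1), c(0, 0, 0)), "collinear")
  # tilted truncation: rotate the phantom by 10 degrees
  R <- rot3(c(1, 0, 0), 10 * pi / 180)
  pht <- generate_mask(small_phantom_spec(pose = list(R = R,
                                                      t = c(0, 0, 0))))
  dt <- analyze_shape(pht$mask)
  want_n <- as.numeric(R %*% c(0, 0, 1))
  ang <- acos(min(abs(sum(dt$basal_plane$normal * want_n)), 1)) * 180 / pi
  expect_lt(ang, 2)
})

test_that("axes: orthonormal right-handed frame, rotation equivariance", {
  ps <- small_phantom_spec()
  d0 <- analyze_shape(generate_mask(ps)$mask)
  M <- cbind(d0$axis_lr, d0$axis_third, d0$axis_long)
  expect_lt(max(abs(crossprod(M) - diag(3))), 1e-8)
  expect_gt(det(M), 0)
  ang <- acos(min(abs(d0$axis_long[3]), 1)) * 180 / pi
  expect_lt(ang, 1)   # axis-aligned phantom -> long axis ~ z
  R <- rot3(c(0.3, 1, 0.2), 15 * pi / 180)
  dr <- analyze_shape(generate_mask(
    small_phantom_spec(pose = list(R = R, t = c(2, 1, -3))))$mask)
  want <- as.numeric(R %*% d0$axis_long)
  ang2 <- acos(min(abs(sum(dr$axis_long * want)), 1)) * 180 / pi
  expect_lt(ang2, 2)
})

test_that("sparse masks define the long axis by the slice normal", {
  ph <- generate_mask(small_phantom_spec())
  sp <- sparsify(ph$mask, 8)
  d <- analyze_shape(sp)
  expect_equal(abs(d$axis_long), c(0, 0, 1))
})

test_that("dimension measurement: sqrt(5)*sd recovers a solid ellipsoid", {
  # solid uniform ellipsoid with semi-axes (30, 30, 50) mm at 2 mm voxels
  dims <- c(34, 34, 54)
  idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  pts <- sweep(idx * 2, 2, c(-33, -33, -53), `+`)
  inside <- (pts[, 1] / 30)^2 + (pts[, 2] / 30)^2 + (pts[, 3] / 50)^2 <= 1
  mask <- binary_mask(array(inside, dims), spacing = c(2, 2, 2),
                      origin = c(-33, -33, -53))
  desc <- list(axis_lr = c(1, 0, 0), axis_third = c(0, 1, 0),
               axis_long = c(0, 0, 1), lv_centroid = c(0, 0, 0),
               lv_pool = mask$voxels, rv_pool = NULL,
               basal_plane = list(point = c(0, 0, 50), normal = c(0, 0, 1)))
  out <- measure_dimensions(mask, desc)
  expect_lt(max(abs(out$lv_size - c(30, 30, 50)) / c(30, 30, 50)), 0.05)
})

test_that("wall thickness of a 10 mm shell within one voxel", {
  ps <- phantom_spec("LV", lv_outer_radii = c(30, 30, 45),
                     wall_thickness = 10, spacing = c(1.5, 1.5, 1.5))
  d <- analyze_shape(generate_mask(ps)$mask)
  expect_lt(abs(d$wall_thickness - 10), 1.5)
})

test_that("basal truncation: geometry, offset zero, idempotence", {
  ps <- small_phantom_spec()
  ph <- generate_mask(ps)
  d <- analyze_shape(ph$mask)
  tr5 <- truncate_base(ph$mask, d$basal_plane, 5)
  fg <- ventmesh:::.vox_to_world(ventmesh:::.mask_fg_idx0(tr5), tr5)
  top <- max(fg %*% d$basal_plane$normal)
  plane_off <- sum(d$basal_plane$point * d$basal_plane$normal)
  expect_lt(top, plane_off - 5 + 1e-9)
  expect_gt(top, plane_off - 5 - 2 * max(ps$spacing))
  tr0 <- truncate_base(ph$mask, d$basal_plane, 0)
  fg0 <- ventmesh:::.vox_to_world(ventmesh:::.mask_fg_idx0(tr0), tr0)
  expect_lt(max(fg0 %*% d$basal_plane$normal), plane_off + 1e-9)
  # idempotence
  tr5b <- truncate_base(tr5, d$basal_plane, 5)
  expect_identical(tr5b$voxels, tr5$voxels)
  expect_error(truncate_base(ph$mask, list(point = c(0, 0, -100),
                                           normal = c(0, 0, 1)), 5),
               "more than half")
})

test_that("initial affine: identity, closed-form recovery, no reflection", {
  spec <- small_lv_spec()
  td <- ventmesh:::.template_descriptor(spec)
  aff0 <- initial_affine(td, td)
  expect_lt(max(abs(aff0$A - diag(3))), 1e-9)
  expect_lt(max(abs(aff0$b)), 1e-9)
  R <- rot3(c(1, 0.5, 0.2), 0.7)
  s <- c(1.3, 1.1, 0.9)
  tgt <- td
  tgt$axis_lr <- as.numeric(R %*% td$axis_lr)
  tgt$axis_third <- as.numeric(R %*% td$axis_third)
  tgt$axis_long <- as.numeric(R %*% td$axis_long)
  tgt$scaling <- td$scaling * s
  tgt$lv_centroid <- c(4, -1, 2)
  aff <- initial_affine(td, tgt)
  want <- R %*% diag(s)
  expect_lt(max(abs(aff$A - want)), 1e-6)
  expect_gt(det(aff$A), 0)
  bad <- td
  bad$axis_lr <- c(1, 0.3, 0)
  expect_error(initial_affine(bad, td), "orthonormal")
})

test_that("descriptor equivariance under rigid motion (centroids)", {
  ps <- small_phantom_spec()
  d0 <- analyze_shape(generate_mask(ps)$mask)
  R <- rot3(c(0, 1, 0), 12 * pi / 180)
  tr <- c(4, -6, 3)
  d1 <- analyze_shape(generate_mask(
    small_phantom_spec(pose = list(R = R, t = tr)))$mask)
  want_c <- as.numeric(R %*% d0$lv_centroid + tr)
  expect_lt(max(abs(d1$lv_centroid - want_c)), max(ps$spacing))
})
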