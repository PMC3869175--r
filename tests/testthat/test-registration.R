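# Registration: LoD schedule, identity/translation/inflation recovery,
# sparse domains, rasterization.

test_that("LoD schedule follows the stated pass/spacing rule exactly", {
  s5 <- lod_schedule(5)
  expect_equal(s5$node_spacings, c(10L, 8L, 6L, 4L, 2L))
  expect_equal(s5$passes, 5L)
  s1 <- lod_schedule(1)
  expect_equal(s1$node_spacings, 10L)
  expect_equal(s1$passes, 1L)
  for (lod in 2:4)
    expect_equal(lod_schedule(lod)$node_spacings,
                 c(10L, 8L, 6L, 4L, 2L)[seq_len(lod)])
  expect_error(lod_schedule(0), "1..5")
  expect_error(lod_schedule(6), "1..5")
  # override hook
  expect_equal(lod_schedule(2, node_spacings = c(12L, 9L))$node_spacings,
               c(12L, 9L))
})

test_that("identity registration stays below 0.1 voxel", {
  ph <- generate_mask(small_phantom_spec())
  f <- register(ph$mask, ph$mask, lod_schedule(1))
  fg <- ventmesh:::.vox_to_world(ventmesh:::.mask_fg_idx0(ph$mask), ph$mask)
  u <- field_at(f, fg)
  expect_lt(max(abs(u)) / min(ph$mask$spacing), 0.1)
})

test_that("pure 3-voxel translation recovered within 0.5 voxel", {
  ph <- generate_mask(small_phantom_spec())
  fixed <- ph$mask
  d <- dim(fixed$voxels)
  mv <- array(FALSE, d)
  mv[1:(d[1] - 3), , ] <- fixed$voxels[4:d[1], , ]
  moving <- binary_mask(mv, fixed$spacing, fixed$origin)
  f <- register(fixed, moving, lod_schedule(3))
  fg <- ventmesh:::.vox_to_world(which(mv, arr.ind = TRUE) - 1L, moving)
  u <- field_at(f, fg)
  truth <- c(3 * fixed$spacing[1], 0, 0)
  err_vox <- mean(sqrt(rowSums(sweep(u, 2, truth)^2))) / fixed$spacing[1]
  expect_lt(err_vox, 0.5)
})

test_that("10% radial inflation recovered within 1 voxel at LoD 3", {
  fixed_sp <- small_phantom_spec(
    deformation = list(type = "affine", A = diag(3) * 1.1))
  phf <- generate_mask(fixed_sp)
  phm <- generate_mask(small_phantom_spec(), grid = phf$mask)
  f <- register(phf$mask, phm$mask, lod_schedule(3))
  fg <- ventmesh:::.vox_to_world(ventmesh:::.mask_fg_idx0(phm$mask),
                                 phm$mask)
  u <- field_at(f, fg)
  u_true <- 0.1 * fg   # x -> 1.1 x about the origin
  err_vox <- mean(sqrt(rowSums((u - u_true)^2))) / phf$mask$spacing[1]
  expect_lt(err_vox, 1)
})

test_that("registration rejects mismatched grids and disjoint images", {
  ph <- generate_mask(small_phantom_spec())
  sm <- array(FALSE, c(10, 10, 10))
  sm[4:6, 4:6, 4:6] <- TRUE
  small <- binary_mask(sm, ph$mask$spacing, ph$mask$origin)
  expect_error(register(ph$mask, small), "share one grid")
  far <- array(FALSE, dim(ph$mask$voxels))
  far[1:2, 1:2, 1:2] <- TRUE
  expect_error(register(ph$mask, binary_mask(far, ph$mask$spacing,
                                             ph$mask$origin)),
               "no overlap")
})

test_that("sparse domain: near-isotropic rebuild and slice counting", {
  # 8 slices at 9 mm slice distance on a 1.5 mm in-plane grid
  vox <- array(FALSE, c(20, 20, 8))
  vox[5:15, 5:15, 2:7] <- TRUE
  m <- binary_mask(vox, spacing = c(1.5, 1.5, 9), origin = c(0, 0, 0),
                   data_slices = 1:8, slice_axis = 3L)
  sd <- build_sparse_domain(m)
  expect_equal(dim(sd$mask$voxels)[3], (8 - 1) * 6 + 1)
  expect_equal(sd$mask$spacing[3], 1.5)
  expect_equal(sd$mask$data_slices, seq(1, 43, by = 6))
  expect_equal(sum(sd$domain), 20 * 20 * 8)
  # domain restricted to exactly the original planes
  expect_true(all(apply(sd$domain[, , sd$mask$data_slices], 3, all)))
  # already-dense data slices: domain is the whole grid
  md <- binary_mask(vox, spacing = c(1.5, 1.5, 1.5),
                    data_slices = 1:8, slice_axis = 3L)
  sdd <- build_sparse_domain(md)
  expect_equal(sum(sdd$domain), prod(dim(vox)))
  expect_error(build_sparse_domain(binary_mask(vox, c(1, 1, 9))),
               "no data_slices")
})

test_that("rasterization: volume oracle and convergence under refinement", {
  m <- small_lv()
  g1 <- list(dims = c(60L, 60L, 70L), spacing = c(1, 1, 1),
             origin = c(-30, -30, -45))
  r1 <- rasterize_mesh(m, g1)
  v1 <- sum(r1$voxels)
  vm <- mesh_volume(m)
  expect_lt(abs(v1 - vm) / vm, 0.02)
  g2 <- list(dims = c(120L, 120L, 140L), spacing = c(0.5, 0.5, 0.5),
             origin = c(-30, -30, -45))
  v2 <- sum(rasterize_mesh(m, g2)$voxels) * 0.125
  expect_lt(abs(v2 - v1) / v1, 0.01)
})

test_that("inverse-consistency on a smooth phantom pair", {
  psB <- small_phantom_spec(
    deformation = list(type = "bump", amplitude = 2, wavelength = 50,
                       axis = 1, along = 3))
  phB <- generate_mask(psB)
  Ap <- generate_mask(small_phantom_spec(), grid = phB$mask)$mask
  Bp <- phB$mask
  fAB <- register(Ap, Bp, lod_schedule(2))
  fBA <- register(Bp, Ap, lod_schedule(2))
  fg <- ventmesh:::.vox_to_world(ventmesh:::.mask_fg_idx0(Bp), Bp)
  u1 <- field_at(fAB, fg)
  u2 <- field_at(fBA, fg + u1)
  comp <- sqrt(rowSums((u1 + u2)^2))
  expect_lt(mean(comp) / min(Ap$spacing), 1)
})

test_that("post-registration SSD does not increase with LoD", {
  ps <- small_phantom_spec(
    deformation = list(type = "bump", amplitude = 2.5, wavelength = 45,
                       axis = 2, along = 3))
  fx <- generate_mask(ps)$mask
  mv <- generate_mask(small_phantom_spec(), grid = fx)$mask
  ssd <- vapply(c(1L, 3L), function(lod)
    utils::tail(register(fx, mv, lod_schedule(lod))$ssd_pass, 1), 0)
  expect_lt(ssd[2], ssd[1] * 1.05)
})
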