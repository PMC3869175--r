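# Shared fixtures: all built in code at test time.

# single-element mesh whose DOFs encode the affine map x -> A x + b on the
# unit cube (value DOFs = A corner + b, first derivatives = columns of A,
# mixed derivatives = 0)
make_affine_element <- function(A = diag(3), b = c(0, 0, 0)) {
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dofs <- array(0, c(8, 8, 3))
  for (n in 1:8) {
    dofs[n, 1, ] <- as.numeric(A %*% corners[n, ] + b)
    dofs[n, 2, ] <- A[, 1]
    dofs[n, 3, ] <- A[, 2]
    dofs[n, 4, ] <- A[, 3]
  }
  hermite_mesh(dofs, matrix(1:8, 1, 8),
               resolution = c(radial = 1L, circ = 1L, long = 1L),
               surface_faces = list(all = cbind(element = rep(1L, 6),
                                                face = 1:6)))
}

# compact LV template used across algebra tests
small_lv_spec <- function(resolution = c(1, 8, 4)) {
  template_spec("LV", resolution = resolution,
                lv_outer_radii = c(26, 25, 40), lv_wall_thickness = 8)
}

small_lv <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthesize_lv(small_lv_spec())
    cache
  }
})

# small, fast phantom (coarse voxels)
small_phantom_spec <- function(...) {
  phantom_spec("LV", lv_outer_radii = c(26, 26, 40), wall_thickness = 9,
               spacing = c(2, 2, 2), margin_mm = 8, ...)
}

# random rotation matrix from a fixed stream
rot3 <- function(axis, angle) {
  ax <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# apply a rigid/affine map to every DOF of a mesh (test-side reference)
affine_mesh <- function(mesh, A, b = c(0, 0, 0)) {
  transform_mesh(mesh, list(A = A, b = b))
}
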