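# BinaryMask container and voxel-grid utilities. World coordinates follow
# the axis-aligned convention: world = origin + (index0) * spacing, with
# 0-based voxel indices (R arrays are addressed 1-based; conversion happens
# here). Direction matrices are assumed pre-applied by the reader.

#' Binary voxel mask
#'
#' @param voxels logical (or coercible) 3-D array; `TRUE` = myocardium.
#' @param spacing voxel spacing in mm (length 3, positive).
#' @param origin world position of voxel (1,1,1) centre, mm.
#' @param data_slices optional integer indices (1-based) of slices along
#'   `slice_axis` that carry original data (sparse acquisitions).
#' @param slice_axis axis of the slice stack (default 3).
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        data_slices = NULL, slice_axis = 3L) {
  v <- array(as.logical(voxels), dim = dim(voxels))
  if (length(dim(v)) != 3L) stop("voxels must be a 3-D array")
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (!any(v)) stop("mask has no foreground voxel")
  structure(list(voxels = v, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 data_slices = if (is.null(data_slices)) NULL
                               else as.integer(data_slices),
                 slice_axis = as.integer(slice_axis)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %s voxels @ (%s) mm, %d foreground%s\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", "),
              sum(x$voxels),
              if (is.null(x$data_slices)) ""
              else sprintf(", %d data slices", length(x$data_slices))))
  invisible(x)
}

# 0-based voxel index matrix of foreground voxels
.mask_fg_idx0 <- function(mask) {
  which(mask$voxels, arr.ind = TRUE) - 1L
}

# world coordinates (mm) of 0-based voxel indices
.vox_to_world <- function(idx0, mask) {
  sweep(sweep(idx0, 2, mask$spacing, `*`), 2, mask$origin, `+`)
}

# world -> continuous 0-based voxel coordinates
.world_to_vox <- function(pts, mask) {
  sweep(sweep(pts, 2, mask$origin, `-`), 2, mask$spacing, `/`)
}

# Euclidean distance transform (mm) to the mask foreground
.edt_mm <- function(vox, spacing) {
  sqrt(.c_edt_sq(as.logical(vox), dim(vox), spacing))
}

# morphological erosion / dilation by a Euclidean ball of radius r_mm
.erode <- function(vox, spacing, r_mm) {
  d <- .edt_mm(!vox, spacing)           # distance to background
  array(vox & d > r_mm, dim = dim(vox))
}

.dilate <- function(vox, spacing, r_mm) {
  d <- .edt_mm(vox, spacing)
  array(vox | d <= r_mm, dim = dim(vox))
}

# separable Gaussian smoothing (sigma in voxels per axis); truncation 3 sigma
.gauss3 <- function(arr, sigma) {
  sigma <- rep(sigma, length.out = 3)
  out <- arr * 1.0
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    k <- k / sum(k)
    out <- .conv_axis(out, k, ax)
  }
  out
}

# convolve along one axis with a symmetric kernel, replicate padding
.conv_axis <- function(arr, k, ax) {
  d <- dim(arr)
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  r <- (length(k) - 1L) %/% 2L
  n <- da[1]
  acc <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    rows <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate boundary
    acc <- acc + k[j] * m[rows, , drop = FALSE]
  }
  a <- array(acc, da)
  aperm(a, order(perm))
}

# connected components, 6-connectivity; returns integer array (0 background),
# labels ordered by decreasing size
.label6 <- function(vox) {
  array(.c_label6(as.logical(vox), dim(vox)), dim = dim(vox))
}
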