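# Minimal NIfTI-1 and MetaImage readers/writers.
#
# No NIfTI/MetaImage package exists in the dependency baseline, so the subset
# of the two formats needed for axis-aligned binary masks and vector fields
# is implemented directly: NIfTI-1 single-file .nii / .nii.gz with uint8,
# int16, int32, float32, float64 data, little- or big-endian, scale
# slope/intercept honoured; MetaImage .mhd (+ .raw) or self-contained .mha
# with MET_UCHAR/MET_SHORT/MET_INT/MET_FLOAT/MET_DOUBLE. Direction/rotation
# matrices are NOT applied: grids are assumed axis-aligned (a documented
# precondition of the pipeline); spacing and offset are honoured.

.nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

.open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a volumetric image (NIfTI-1 or MetaImage)
#'
#' Returns the raw array plus grid geometry; use [read_mask()] to get a
#' thresholded [binary_mask()].
#'
#' @param path `.nii`, `.nii.gz`, `.mhd` or `.mha` file.
#' @return list with `data` (numeric array), `spacing`, `origin`.
#' @export
read_volume <- function(path) {
  if (grepl("\\.(mhd|mha)$", path, ignore.case = TRUE))
    return(.read_metaimage(path))
  .read_nifti(path)
}

.read_nifti <- function(path) {
  con <- .open_maybe_gz(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- "little"
  if (sz != 348L) {
    sz_b <- .swap_int32(sz)
    if (sz_b != 348L) stop("not a NIfTI-1 file: ", path)
    endian <- "big"
  }
  hdr <- readBin(con, "raw", 344)
  rd_i16 <- function(off, n = 1) readBin(hdr[(off - 4 + 1):344], "integer",
                                         n, size = 2, endian = endian)
  rd_f32 <- function(off, n = 1) readBin(hdr[(off - 4 + 1):344], "double",
                                         n, size = 4, endian = endian)
  dim0 <- rd_i16(40, 8)
  datatype <- rd_i16(70)
  pixdim <- rd_f32(76, 8)
  vox_offset <- rd_f32(108)
  scl_slope <- rd_f32(112)
  scl_inter <- rd_f32(116)
  qform_code <- rd_i16(252)
  sform_code <- rd_i16(254)
  srow <- matrix(rd_f32(280, 12), 3, 4, byrow = TRUE)
  magic <- rawToChar(hdr[341:343])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic: ", magic)
  nd <- dim0[1]
  dims <- dim0[2:(1 + max(nd, 3))]
  dims[dims == 0] <- 1L
  nx <- dims[1]; ny <- dims[2]; nz <- if (length(dims) >= 3) dims[3] else 1L
  ncomp <- if (nd >= 5) max(dim0[6], 1L) else 1L
  info <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(info)) stop("unsupported NIfTI datatype: ", datatype)
  skip <- vox_offset - 348   # consume the extension flag + any extensions
  if (skip > 0) readBin(con, "raw", skip)
  n <- as.numeric(nx) * ny * nz * ncomp
  vals <- readBin(con, info$what, n, size = info$size, signed = info$signed,
                  endian = endian)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  spacing <- abs(pixdim[2:4])
  spacing[spacing == 0] <- 1
  origin <- c(0, 0, 0)
  if (sform_code > 0) origin <- srow[, 4]
  else if (qform_code > 0) origin <- rd_f32(268, 3)
  data <- if (ncomp > 1) array(vals, c(nx, ny, nz, ncomp))
          else array(vals, c(nx, ny, nz))
  list(data = data, spacing = spacing, origin = origin)
}

.swap_int32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4, endian = "little")
  readBin(rev(b), "integer", 1, size = 4, endian = "little")
}

#' Read a binary mask from NIfTI or MetaImage
#'
#' Any voxel with value above `threshold` (default: nonzero) is foreground.
#'
#' @param path image path.
#' @param threshold foreground threshold (exclusive), default 0.
#' @param data_slices,slice_axis passed through to [binary_mask()].
#' @return a [binary_mask()].
#' @export
read_mask <- function(path, threshold = 0, data_slices = NULL,
                      slice_axis = 3L) {
  v <- read_volume(path)
  if (length(dim(v$data)) != 3L) stop("mask image must be 3-D")
  binary_mask(v$data > threshold, spacing = v$spacing, origin = v$origin,
              data_slices = data_slices, slice_axis = slice_axis)
}

#' Write a volume (or binary mask / vector field) as NIfTI-1
#'
#' @param x a [binary_mask()], a 3-D numeric array, or a 4-D array whose 4th
#'   dimension is a vector component (written as a NIfTI 5-D vector volume).
#' @param path output `.nii` or `.nii.gz` path.
#' @param spacing,origin grid geometry; taken from the mask when `x` is a
#'   [binary_mask()].
#' @return invisibly, `path`.
#' @export
write_nifti <- function(x, path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (inherits(x, "binary_mask")) {
    spacing <- x$spacing; origin <- x$origin
    data <- array(as.integer(x$voxels), dim(x$voxels))
    datatype <- 2L; bitpix <- 8L; size <- 1L; what <- "integer"
  } else {
    data <- x
    datatype <- 64L; bitpix <- 64L; size <- 8L; what <- "double"
  }
  d <- dim(data)
  is_vec <- length(d) == 4L
  dim0 <- integer(8)
  dim0[1] <- if (is_vec) 5L else 3L
  dim0[2:4] <- d[1:3]
  dim0[5] <- 1L
  dim0[6] <- if (is_vec) d[4] else 1L
  dim0[7:8] <- 1L
  dim0[dim0 == 0] <- 1L
  con <- .open_maybe_gz(path, "wb")
  on.exit(close(con))
  wi32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wi16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  wf32 <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wi32(348L)                         # sizeof_hdr
  wraw(36)                           # data_type, db_name, extents, ...
  wi16(dim0)                         # dim[8]
  wf32(c(0, 0, 0))                   # intent_p1..p3
  wi16(if (is_vec) 1007L else 0L)    # intent_code (vector)
  wi16(datatype)
  wi16(bitpix)
  wi16(0L)                           # slice_start
  wf32(c(0, spacing, 1, 1, 1, 1))    # pixdim[8] (qfac 0)
  wf32(352)                          # vox_offset
  wf32(1); wf32(0)                   # scl_slope, scl_inter
  wi16(0L); writeBin(as.raw(c(0, 0)), con)  # slice_end, slice_code, xyzt
  wf32(0); wf32(0)                   # cal_max, cal_min
  wf32(0); wf32(0)                   # slice_duration, toffset
  wi32(0L); wi32(0L)                 # glmax, glmin
  wraw(80); wraw(24)                 # descrip, aux_file
  wi16(0L); wi16(1L)                 # qform_code, sform_code
  wf32(c(0, 0, 0))                   # quatern b, c, d
  wf32(origin)                       # qoffset x, y, z
  wf32(c(spacing[1], 0, 0, origin[1]))
  wf32(c(0, spacing[2], 0, origin[2]))
  wf32(c(0, 0, spacing[3], origin[3]))
  wraw(16)                           # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)   # magic
  wraw(4)                            # extension flag
  writeBin(if (what == "integer") as.integer(data) else as.numeric(data),
           con, size = size, endian = "little")
  invisible(path)
}

.meta_dtypes <- c(MET_UCHAR = "2", MET_SHORT = "4", MET_INT = "8",
                  MET_FLOAT = "16", MET_DOUBLE = "64")

.read_metaimage <- function(path) {
  # header is text until (and including) the ElementDataFile line
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- character()
  repeat {
    line <- ""
    repeat {
      ch <- readBin(con, "raw", 1)
      if (!length(ch) || ch == as.raw(10)) break
      line <- paste0(line, rawToChar(ch))
    }
    hdr <- c(hdr, line)
    if (grepl("^\\s*ElementDataFile", line)) break
    if (!length(ch)) stop("malformed MetaImage header")
  }
  kv <- strsplit(hdr, "\\s*=\\s*")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  get <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing",
                                     get("ElementSize", "1 1 1")),
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset", get("Position", "0 0 0")),
                                "\\s+")[[1]])
  et <- get("ElementType", "MET_UCHAR")
  msb <- identical(toupper(get("BinaryDataByteOrderMSB", "FALSE")), "TRUE") ||
         identical(toupper(get("ElementByteOrderMSB", "FALSE")), "TRUE")
  info <- .nifti_dtypes[[.meta_dtypes[[et]]]]
  if (is.null(info)) stop("unsupported MetaImage ElementType: ", et)
  datafile <- get("ElementDataFile")
  n <- prod(dims)
  if (identical(datafile, "LOCAL")) {
    vals_ <- readBin(con, info$what, n, size = info$size,
                     signed = info$signed,
                     endian = if (msb) "big" else "little")
  } else {
    dpath <- file.path(dirname(path), datafile)
    dcon <- file(dpath, "rb")
    on.exit(close(dcon), add = TRUE)
    vals_ <- readBin(dcon, info$what, n, size = info$size,
                     signed = info$signed,
                     endian = if (msb) "big" else "little")
  }
  list(data = array(vals_, dims), spacing = spacing, origin = origin)
}

#' Write a binary mask as MetaImage
#'
#' `.mha` embeds the data (`ElementDataFile = LOCAL`); `.mhd` writes a
#' sibling `.raw` file.
#'
#' @param mask a [binary_mask()].
#' @param path output `.mha` or `.mhd` path.
#' @return invisibly, `path`.
#' @export
write_metaimage <- function(mask, path) {
  local <- grepl("\\.mha$", path, ignore.case = TRUE)
  d <- dim(mask$voxels)
  datafile <- if (local) "LOCAL"
              else sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =", paste(mask$spacing, collapse = " ")),
           paste("Offset =", paste(mask$origin, collapse = " ")),
           "ElementType = MET_UCHAR",
           paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  payload <- as.raw(as.integer(mask$voxels))
  if (local) writeBin(payload, con)
  else {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(payload, rcon)
  }
  invisible(path)
}
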