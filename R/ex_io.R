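# EX (exnode/exelem) and legacy-ASCII VTK writers.
#
# EX dialect note: EX files in the wild vary by vendor. The writer below
# emits a minimal exnode/exelem pair following the cmGui field template for a
# 3-component rectangular-cartesian coordinate field with tricubic Hermite
# basis: each node carries the value and 7 derivatives per component in
# cmGui derivative order (d/ds1, d/ds2, d2/ds1ds2, d/ds3, d2/ds1ds3,
# d2/ds2ds3, d3/ds1ds2ds3); each element lists its 8 nodes in tensor-product
# order. read_ex() parses exactly this dialect; values are printed with 17
# significant digits so a round trip reproduces the DOFs bit-exactly.

# internal DOF order -> cmGui derivative order
.EX_ORDER <- c(1L, 2L, 3L, 5L, 4L, 6L, 7L, 8L)

.fmt17 <- function(x) formatC(x, format = "g", digits = 17)

#' Write a mesh as EX (exnode + exelem) text files
#'
#' @param mesh a [hermite_mesh()].
#' @param path output path prefix; `<path>.exnode` and `<path>.exelem` are
#'   written.
#' @return invisibly, the two file paths.
#' @export
write_ex <- function(mesh, path) {
  nn <- dim(mesh$dofs)[1]
  ne <- nrow(mesh$elements)
  node_file <- paste0(path, ".exnode")
  elem_file <- paste0(path, ".exelem")
  con <- file(node_file, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    " Group name: ventmesh",
    " #Fields=1",
    " 1) coordinates, coordinate, rectangular cartesian, #Components=3",
    paste0("   x.  Value index= 1, #Derivatives=7 (d/ds1,d/ds2,d2/ds1ds2,",
           "d/ds3,d2/ds1ds3,d2/ds2ds3,d3/ds1ds2ds3)"),
    paste0("   y.  Value index= 9, #Derivatives=7 (d/ds1,d/ds2,d2/ds1ds2,",
           "d/ds3,d2/ds1ds3,d2/ds2ds3,d3/ds1ds2ds3)"),
    paste0("   z.  Value index=17, #Derivatives=7 (d/ds1,d/ds2,d2/ds1ds2,",
           "d/ds3,d2/ds1ds3,d2/ds2ds3,d3/ds1ds2ds3)")
  ), con)
  for (i in seq_len(nn)) {
    writeLines(sprintf(" Node: %d", i), con)
    for (coord in 1:3)
      writeLines(paste0("  ",
        paste(.fmt17(mesh$dofs[i, .EX_ORDER, coord]), collapse = " ")), con)
  }
  con2 <- file(elem_file, "w")
  on.exit(close(con2), add = TRUE)
  writeLines(c(
    " Group name: ventmesh",
    " Shape.  Dimension=3",
    " #Scale factor sets=0",
    " #Nodes=8",
    " #Fields=1",
    " 1) coordinates, coordinate, rectangular cartesian, #Components=3",
    "   basis=c.Hermite*c.Hermite*c.Hermite",
    sprintf(" !ventmesh topology=%s apex=%s resolution=%s",
            mesh$topology, mesh$apex_style,
            paste(mesh$resolution, collapse = ","))
  ), con2)
  for (e in seq_len(ne)) {
    writeLines(sprintf(" Element: %d 0 0", e), con2)
    writeLines("   Nodes:", con2)
    writeLines(paste0("     ",
      paste(mesh$elements[e, ], collapse = " ")), con2)
  }
  if (length(mesh$tie_groups)) {
    writeLines(" !ties", con2)
    for (g in mesh$tie_groups)
      writeLines(paste0("   ", paste(g, collapse = " ")), con2)
  }
  for (lbl in names(mesh$surface_faces)) {
    fc <- mesh$surface_faces[[lbl]]
    writeLines(sprintf(" !faces %s", lbl), con2)
    writeLines(paste0("   ", fc[, 1], " ", fc[, 2]), con2)
  }
  invisible(c(node_file, elem_file))
}

#' Read a mesh written by [write_ex()]
#'
#' Parses the minimal EX dialect documented in this package; not a general
#' EX reader.
#'
#' @param path path prefix used in [write_ex()].
#' @return a [hermite_mesh()].
#' @export
read_ex <- function(path) {
  node_lines <- readLines(paste0(path, ".exnode"))
  elem_lines <- readLines(paste0(path, ".exelem"))
  node_at <- grep("^ Node: ", node_lines)
  nn <- length(node_at)
  dofs <- array(0, c(nn, 8L, 3L))
  inv_order <- order(.EX_ORDER)
  for (idx in seq_len(nn)) {
    i <- as.integer(sub("^ Node: ", "", node_lines[node_at[idx]]))
    for (coord in 1:3) {
      vals <- as.numeric(strsplit(trimws(
        node_lines[node_at[idx] + coord]), "\\s+")[[1]])
      dofs[i, , coord] <- vals[inv_order]
    }
  }
  meta <- grep("^ !ventmesh ", elem_lines, value = TRUE)
  topology <- sub(".*topology=(\\S+).*", "\\1", meta)
  apex <- sub(".*apex=(\\S+).*", "\\1", meta)
  res <- as.integer(strsplit(sub(".*resolution=(\\S+).*", "\\1", meta),
                             ",")[[1]])
  elem_at <- grep("^ Element: ", elem_lines)
  elements <- t(vapply(elem_at, function(l)
    as.integer(strsplit(trimws(elem_lines[l + 2L]), "\\s+")[[1]]),
    integer(8)))
  ties <- list()
  tie_at <- grep("^ !ties", elem_lines)
  faces <- list()
  face_at <- grep("^ !faces ", elem_lines)
  stops <- sort(c(face_at, length(elem_lines) + 1L))
  if (length(tie_at)) {
    end <- min(stops[stops > tie_at])
    for (l in seq(tie_at + 1L, end - 1L))
      ties[[length(ties) + 1L]] <-
        as.integer(strsplit(trimws(elem_lines[l]), "\\s+")[[1]])
  }
  for (fi in seq_along(face_at)) {
    lbl <- sub("^ !faces ", "", elem_lines[face_at[fi]])
    end <- if (fi < length(face_at)) face_at[fi + 1L]
           else length(elem_lines) + 1L
    rows <- t(vapply(seq(face_at[fi] + 1L, end - 1L), function(l)
      as.integer(strsplit(trimws(elem_lines[l]), "\\s+")[[1]]), integer(2)))
    colnames(rows) <- c("element", "face")
    faces[[lbl]] <- rows
  }
  hermite_mesh(dofs, elements, topology = topology,
               resolution = stats::setNames(res, c("radial", "circ", "long")),
               apex_style = apex, surface_faces = faces, tie_groups = ties)
}

#' Write a subdivided hexahedral visualization mesh (legacy ASCII VTK)
#'
#' Each Hermite element is evaluated on a `(subdivision+1)^3` lattice and
#' written as `subdivision^3` linear hexahedral cells.
#'
#' @param mesh a [hermite_mesh()].
#' @param path output `.vtk` path.
#' @param subdivision linear cells per element per axis (default 3).
#' @return invisibly, `path`.
#' @export
write_vtk <- function(mesh, path, subdivision = 3L) {
  s <- as.integer(subdivision)
  stopifnot(s >= 1L)
  ticks <- seq(0, 1, length.out = s + 1L)
  grid <- as.matrix(expand.grid(x1 = ticks, x2 = ticks, x3 = ticks))
  ne <- nrow(mesh$elements)
  npts_e <- (s + 1L)^3
  pts <- matrix(0, ne * npts_e, 3)
  for (e in seq_len(ne))
    pts[(e - 1L) * npts_e + seq_len(npts_e), ] <-
      evaluate_element(mesh, e, grid)
  # cell connectivity within one element lattice (0-based, VTK hexa order)
  lid <- function(i, j, k) i + (s + 1L) * (j + (s + 1L) * k)
  cells0 <- matrix(0L, s^3, 8L)
  r <- 1L
  for (k in 0:(s - 1L)) for (j in 0:(s - 1L)) for (i in 0:(s - 1L)) {
    cells0[r, ] <- c(lid(i, j, k), lid(i + 1L, j, k), lid(i + 1L, j + 1L, k),
                     lid(i, j + 1L, k), lid(i, j, k + 1L),
                     lid(i + 1L, j, k + 1L), lid(i + 1L, j + 1L, k + 1L),
                     lid(i, j + 1L, k + 1L))
    r <- r + 1L
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "ventmesh subdivided hexahedral mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(pts))), con)
  writeLines(paste(.fmt17(pts[, 1]), .fmt17(pts[, 2]), .fmt17(pts[, 3])),
             con)
  ncell <- ne * s^3
  writeLines(sprintf("CELLS %d %d", ncell, ncell * 9L), con)
  for (e in seq_len(ne)) {
    off <- (e - 1L) * npts_e
    writeLines(paste(8L, apply(cells0 + off, 1, paste, collapse = " ")),
               con)
  }
  writeLines(sprintf("CELL_TYPES %d", ncell), con)
  writeLines(as.character(rep(12L, ncell)), con)
  invisible(path)
}
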