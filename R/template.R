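# Truncated-ellipsoid template synthesis.
#
# Geometry model: the LV wall is the shell between two coaxial ellipsoids
# (inner semi-axes = outer - wall thickness), truncated by the flat basal
# plane z = base_height (the local xi2 = 1 face of the top element row). The
# global parameterization used to generate nodal DOFs is
#   g1 in [0,1] circumferential (phi = 2*pi*g1),
#   g2 in [0,1] longitudinal (theta = g2 * theta_max(g3), apex -> base),
#   g3 in [0,1] transmural (endo -> epi),
# with theta_max(g3) chosen per layer so every layer ends on the same flat
# base plane. Elements split this parameter box uniformly; nodal derivative
# DOFs are partial derivatives of the analytic map with respect to
# element-local (unit) coordinates, computed by central finite differences of
# the analytic map (the map is analytic in all parameters, including slightly
# outside [0,1], so central stencils are valid everywhere).
#
# The BiV template adds an RV free wall: a shell lifted off the LV
# epicardium by a smooth bulge that vanishes on the squared insertion line
# (two meridional sides and the bottom), with the exact ellipsoid normal as
# the lift direction. Insertion-line nodes coincide with LV epicardial
# nodes; they are distinct storage nodes tied to a common position.

#' Template specification
#'
#' @param topology `"LV"` or `"BiV"`.
#' @param resolution integer triple: elements in (radial, circumferential,
#'   longitudinal) direction of the LV wall.
#' @param apex_style `"collapsed"` (default) or `"hole"`; `"patch"` is not
#'   implemented.
#' @param lv_outer_radii outer ellipsoid semi-axes (mm), order (left-right,
#'   third, long).
#' @param lv_wall_thickness wall thickness (mm).
#' @param base_height height of the flat basal plane above the ellipsoid
#'   centre (mm); default `0.35 * lv_outer_radii[3]`.
#' @param rv_size RV free-wall dimensions (mm): `[1]` maximal lift of the RV
#'   epicardium off the LV epicardium.
#' @param rv_insertion_level fraction of the LV long axis (from the base)
#'   where the RV apex inserts, in (0,1).
#' @param rv_wall_thickness RV free-wall thickness (mm).
#' @param rv_angle angular span of the RV insertion around the LV long axis
#'   (radians).
#' @param apex_hole_angle polar angle of the apical hole rim (radians), used
#'   only for `apex_style = "hole"`.
#' @param truncate_base whether the source mask should be truncated below
#'   the basal plane before fitting.
#' @param basal_offset truncation offset below the basal plane (mm).
#' @return object of class `template_spec`.
#' @export
template_spec <- function(topology = c("LV", "BiV"),
                          resolution = c(radial = 1L, circ = 12L, long = 6L),
                          apex_style = c("collapsed", "hole", "patch"),
                          lv_outer_radii = c(35, 35, 55),
                          lv_wall_thickness = 10,
                          base_height = NULL,
                          rv_size = c(22, 25, 50),
                          rv_insertion_level = 0.75,
                          rv_wall_thickness = 4,
                          rv_angle = 0.45 * 2 * pi,
                          apex_hole_angle = 0.25,
                          truncate_base = TRUE,
                          basal_offset = 5) {
  topology <- match.arg(topology)
  apex_style <- match.arg(apex_style)
  resolution <- stats::setNames(as.integer(resolution),
                                c("radial", "circ", "long"))
  if (any(resolution < 1L)) stop("resolution counts must be positive")
  if (resolution["circ"] < 3L) stop("need at least 3 circumferential elements")
  if (lv_wall_thickness <= 0 || lv_wall_thickness >= min(lv_outer_radii))
    stop("wall thickness must be positive and smaller than every radius")
  if (is.null(base_height)) base_height <- 0.35 * lv_outer_radii[3]
  c_in <- lv_outer_radii[3] - lv_wall_thickness
  if (base_height >= c_in)
    stop("base_height must be below the inner apex height")
  if (topology == "BiV") {
    if (rv_insertion_level <= 0 || rv_insertion_level >= 1)
      stop("rv_insertion_level must be in (0,1)")
    if (rv_size[3] > lv_outer_radii[3] + base_height)
      stop("RV longer than LV")
    if (rv_wall_thickness >= rv_size[1])
      stop("RV wall thicker than RV size")
  }
  structure(list(
    topology = topology, resolution = resolution, apex_style = apex_style,
    lv_outer_radii = as.numeric(lv_outer_radii),
    lv_wall_thickness = lv_wall_thickness,
    base_height = base_height, rv_size = as.numeric(rv_size),
    rv_insertion_level = rv_insertion_level,
    rv_wall_thickness = rv_wall_thickness, rv_angle = rv_angle,
    apex_hole_angle = apex_hole_angle,
    truncate_base = truncate_base, basal_offset = basal_offset
  ), class = "template_spec")
}

#' Serialize / parse a template spec as key=value text
#' @param spec a [template_spec()]; `path` output file.
#' @return `write_template_spec` the path; `read_template_spec` the spec.
#' @export
write_template_spec <- function(spec, path) {
  vals <- vapply(spec, function(v) paste(format(v, digits = 17),
                                         collapse = ","), "")
  writeLines(paste0(names(spec), "=", vals), path)
  invisible(path)
}

#' @rdname write_template_spec
#' @export
read_template_spec <- function(path) {
  ln <- readLines(path)
  kv <- strsplit(ln, "=", fixed = TRUE)
  args <- stats::setNames(lapply(kv, function(p) {
    parts <- strsplit(p[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (any(is.na(num))) {
      if (identical(parts, "TRUE")) TRUE
      else if (identical(parts, "FALSE")) FALSE
      else parts
    } else num
  }), vapply(kv, `[`, "", 1))
  do.call(template_spec, args)
}

# Volume-equalizing parameter profiles. With uniform parameter spacing the
# volume differential det J varies strongly within elements (transmurally
# by the growth of the layer area, longitudinally by the sin(theta) factor
# towards the apex), which depresses the Jacobian-ratio quality of an
# ideal template. Both directions are therefore reparameterized so the
# volume differential is near-constant per unit parameter:
#  - transmural: inverse of the cumulative layer-volume weight
#    w3(s) = (a_in + t s)(b_in + t s)(c_in + t s) (closed-form quartic);
#  - longitudinal: inverse of W2(theta) = (1 - cos theta) + delta * theta,
#    the spherical equal-area profile regularized by delta so the slope at
#    the apex stays finite (pure equal-area has a sqrt singularity there,
#    which would blow up the apex derivative DOFs).
# Profiles are smooth and monotone on an extended domain so the central
# finite-difference stencils used for DOF generation remain valid.
.profile_inverse <- function(Wfun, lo = -0.05, hi = 1.05, n = 1201L) {
  s <- seq(lo, hi, length.out = n)
  W <- Wfun(s)
  W0 <- Wfun(0)
  W1 <- Wfun(1)
  u <- (W - W0) / (W1 - W0)
  stats::splinefun(u, s, method = "hyman")
}

.lv_profiles <- function(spec, delta = 0.2) {
  t <- spec$lv_wall_thickness
  a_in <- spec$lv_outer_radii[1] - t
  b_in <- spec$lv_outer_radii[2] - t
  c_in <- spec$lv_outer_radii[3] - t
  W3 <- function(s) {
    # integral of (a_in + t s)(b_in + t s)(c_in + t s)
    p0 <- a_in * b_in * c_in
    p1 <- t * (a_in * b_in + a_in * c_in + b_in * c_in)
    p2 <- t^2 * (a_in + b_in + c_in)
    p3 <- t^3
    p0 * s + p1 * s^2 / 2 + p2 * s^3 / 3 + p3 * s^4 / 4
  }
  h_rad <- .profile_inverse(W3)
  c_mid <- c_in + t / 2
  th_ref <- acos(max(min(-spec$base_height / c_mid, 1), -1))
  W2 <- function(u) (1 - cos(u * th_ref)) + delta * u * th_ref
  f_long <- .profile_inverse(W2)
  list(f_long = f_long, h_rad = h_rad)
}

# analytic LV wall map: g (n x 3 in global parameters) -> positions (n x 3)
.lv_map <- function(spec) {
  a_out <- spec$lv_outer_radii[1]; b_out <- spec$lv_outer_radii[2]
  c_out <- spec$lv_outer_radii[3]
  t <- spec$lv_wall_thickness
  zb <- spec$base_height
  hole <- identical(spec$apex_style, "hole")
  th0 <- if (hole) spec$apex_hole_angle else 0
  pr <- .lv_profiles(spec)
  function(g) {
    g <- matrix(g, ncol = 3)
    r <- pr$h_rad(g[, 3])
    A <- (a_out - t) + t * r
    B <- (b_out - t) + t * r
    C <- (c_out - t) + t * r
    th_max <- acos(pmax(pmin(-zb / C, 1), -1))
    th <- th0 + pr$f_long(g[, 2]) * (th_max - th0)
    phi <- 2 * pi * g[, 1]
    cbind(A * sin(th) * cos(phi), B * sin(th) * sin(phi), -C * cos(th))
  }
}

# All 8 Hermite DOFs at parameter points `g` for an analytic map `F`,
# converted to element-local unit coordinates via per-axis spans.
.dofs_from_map <- function(F, g, spans) {
  g <- matrix(g, ncol = 3)
  n <- nrow(g)
  dofs <- array(0, c(n, 8L, 3L))
  sh <- function(ax, s, h) { gg <- g; gg[, ax] <- gg[, ax] + s * h; gg }
  h1 <- 1e-5; h2 <- 1e-4; h3 <- 2e-3
  sh2 <- function(a, sa, b, sb, h) {
    gg <- g
    gg[, a] <- gg[, a] + sa * h
    gg[, b] <- gg[, b] + sb * h
    gg
  }
  dofs[, 1, ] <- F(g)
  for (d in 1:3) {
    dofs[, 1 + d, ] <- (F(sh(d, 1, h1)) - F(sh(d, -1, h1))) / (2 * h1) *
      spans[d]
  }
  mix2 <- list(c(1L, 2L, 5L), c(1L, 3L, 6L), c(2L, 3L, 7L))
  for (m in mix2) {
    a <- m[1]; b <- m[2]; slot <- m[3]
    dofs[, slot, ] <- (F(sh2(a, 1, b, 1, h2)) - F(sh2(a, 1, b, -1, h2)) -
                       F(sh2(a, -1, b, 1, h2)) + F(sh2(a, -1, b, -1, h2))) /
      (4 * h2^2) * spans[a] * spans[b]
  }
  # triple mixed
  acc <- matrix(0, n, 3)
  for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1)) {
    gg <- g
    gg[, 1] <- gg[, 1] + s1 * h3
    gg[, 2] <- gg[, 2] + s2 * h3
    gg[, 3] <- gg[, 3] + s3 * h3
    acc <- acc + s1 * s2 * s3 * F(gg)
  }
  dofs[, 8, ] <- acc / (8 * h3^3) * prod(spans)
  dofs
}

# node id helper for the structured LV block
.lv_node_id <- function(ic, j, k, nc, nl) ic + nc * (j + (nl + 1L) * k)

#' Synthesize an idealized LV template mesh
#'
#' Builds the truncated-ellipsoid left-ventricular shell described by the
#' spec as a structured tricubic Hermite mesh with collapsed (or open) apex.
#'
#' @param spec a [template_spec()] with `topology = "LV"` (the LV wall of a
#'   BiV spec is also built through this routine).
#' @return a [hermite_mesh()].
#' @export
synthesize_lv <- function(spec) {
  if (!inherits(spec, "template_spec")) stop("invalid spec")
  if (identical(spec$apex_style, "patch"))
    stop("apex_style 'patch' is not implemented")
  nr <- spec$resolution[["radial"]]
  nc <- spec$resolution[["circ"]]
  nl <- spec$resolution[["long"]]
  Fm <- .lv_map(spec)
  # node parameter grid: ic = 1..nc (periodic), j = 0..nl, k = 0..nr
  idx <- expand.grid(ic = seq_len(nc), j = 0:nl, k = 0:nr)
  g <- cbind((idx$ic - 1) / nc, idx$j / nl, idx$k / nr)
  dofs <- .dofs_from_map(Fm, g, spans = c(1 / nc, 1 / nl, 1 / nr))
  collapsed <- identical(spec$apex_style, "collapsed")
  if (collapsed) {
    # exact coincidence of apex ring positions (kill FD noise in phi)
    for (k in 0:nr) {
      rows <- which(idx$j == 0L & idx$k == k)
      apex_pos <- colMeans(dofs[rows, 1, , drop = FALSE][, 1, ])
      for (r in rows) dofs[r, 1, ] <- apex_pos
    }
  }
  elements <- matrix(0L, nr * nc * nl, 8L)
  e <- 0L
  for (kr in seq_len(nr)) for (jl in seq_len(nl)) for (ic in seq_len(nc)) {
    e <- e + 1L
    corners <- integer(8)
    for (cn in 1:8) {
      ici <- ((ic - 1L + .CORNER_I1[cn]) %% nc) + 1L
      corners[cn] <- .lv_node_id(ici, jl - 1L + .CORNER_I2[cn],
                                 kr - 1L + .CORNER_I3[cn], nc, nl)
    }
    elements[e, ] <- corners
  }
  # element index helper (same ordering as the loop above)
  eid <- function(ic, jl, kr) ic + nc * ((jl - 1L) + nl * (kr - 1L))
  endo <- cbind(element = vapply(seq_len(nc * nl), function(q) {
    ic <- ((q - 1L) %% nc) + 1L; jl <- ((q - 1L) %/% nc) + 1L
    eid(ic, jl, 1L)
  }, 1L), face = 5L)
  epi <- cbind(element = vapply(seq_len(nc * nl), function(q) {
    ic <- ((q - 1L) %% nc) + 1L; jl <- ((q - 1L) %/% nc) + 1L
    eid(ic, jl, nr)
  }, 1L), face = 6L)
  base <- do.call(rbind, lapply(seq_len(nr), function(kr)
    cbind(element = vapply(seq_len(nc), function(ic) eid(ic, nl, kr), 1L),
          face = 4L)))
  faces <- list(endo_LV = endo, epi = epi, base = base)
  if (!collapsed)
    faces$apex_hole <- do.call(rbind, lapply(seq_len(nr), function(kr)
      cbind(element = vapply(seq_len(nc), function(ic) eid(ic, 1L, kr), 1L),
            face = 3L)))
  ties <- list()
  if (collapsed)
    ties <- lapply(0:nr, function(k)
      vapply(seq_len(nc), function(ic) .lv_node_id(ic, 0L, k, nc, nl), 1L))
  m <- hermite_mesh(dofs, elements, topology = "LV",
                    resolution = spec$resolution,
                    apex_style = spec$apex_style,
                    surface_faces = faces, tie_groups = ties,
                    regions = rep("LV", nrow(elements)))
  cols <- vector("list", nc * (nl + 1L))
  q <- 1L
  for (j in 0:nl) for (ic in seq_len(nc)) {
    cols[[q]] <- vapply(0:nr, function(k) .lv_node_id(ic, j, k, nc, nl), 1L)
    q <- q + 1L
  }
  m$transmural_columns <- cols
  m
}

#' Synthesize an idealized biventricular template mesh
#'
#' LV shell as in [synthesize_lv()] plus an RV free wall attached along a
#' squared insertion line on the LV epicardium at the requested insertion
#' level. Insertion nodes lie exactly on the LV epicardial surface and are
#' tied (common position) to the corresponding LV nodes. The squared
#' insertion shape follows the template topology and is anatomically
#' imperfect near the RV apex, a documented limitation of this topology.
#'
#' @param spec a [template_spec()] with `topology = "BiV"`.
#' @return a [hermite_mesh()].
#' @export
synthesize_biv <- function(spec) {
  if (!identical(spec$topology, "BiV")) stop("spec topology must be BiV")
  lv <- synthesize_lv(spec)
  nr <- spec$resolution[["radial"]]
  nc <- spec$resolution[["circ"]]
  nl <- spec$resolution[["long"]]
  # RV patch span on the LV node grid: m_c circumferential intervals
  # (even, centred on phi = 0), rows j_ins..nl longitudinally
  m_c <- max(2L, 2L * round(spec$rv_angle / (2 * pi) * nc / 2))
  m_c <- min(m_c, 2L * ((nc - 1L) %/% 2L))
  j_ins <- max(1L, min(nl - 1L,
                       round(nl * (1 - spec$rv_insertion_level))))
  m_l <- nl - j_ins
  d_rv <- spec$rv_size[1]
  tau <- spec$rv_wall_thickness
  a_out <- spec$lv_outer_radii[1]; b_out <- spec$lv_outer_radii[2]
  c_out <- spec$lv_outer_radii[3]
  zb <- spec$base_height
  pr <- .lv_profiles(spec)
  lv_epi <- function(g1, g2) {
    th_max <- acos(pmax(pmin(-zb / c_out, 1), -1))
    th <- pr$f_long(g2) * th_max
    phi <- 2 * pi * g1
    cbind(a_out * sin(th) * cos(phi), b_out * sin(th) * sin(phi),
          -c_out * cos(th))
  }
  epi_normal <- function(p) {
    nrm <- cbind(p[, 1] / a_out^2, p[, 2] / b_out^2, p[, 3] / c_out^2)
    nrm / sqrt(rowSums(nrm^2))
  }
  g1_start <- -(m_c / 2) / nc        # patch centred on phi = 0
  g2_ins <- j_ins / nl
  rv_map <- function(g) {
    g <- matrix(g, ncol = 3)
    g1 <- g1_start + g[, 1] * m_c / nc
    g2 <- g2_ins + g[, 2] * (1 - g2_ins)
    p <- lv_epi(g1, g2)
    nrm <- epi_normal(p)
    bulge <- d_rv * sin(pi * g[, 1]) * sin(pi * g[, 2] / 2)
    b_in <- bulge^2 / (bulge + tau)
    lift <- b_in + g[, 3] * (bulge - b_in)
    p + lift * nrm
  }
  idx <- expand.grid(is = 0:m_c, it = 0:m_l, k = 0:1)
  g <- cbind(idx$is / m_c, idx$it / m_l, idx$k)
  rv_dofs <- .dofs_from_map(rv_map, g, spans = c(1 / m_c, 1 / m_l, 1))
  # snap boundary nodes exactly onto the LV epicardium
  n_lv <- dim(lv$dofs)[1]
  rv_id <- function(is, it, k)
    n_lv + (is + 1L) + (m_c + 1L) * (it + (m_l + 1L) * k)
  on_boundary <- idx$is == 0L | idx$is == m_c | idx$it == 0L
  brows <- which(on_boundary)
  bpos <- lv_epi(g1_start + g[brows, 1] * m_c / nc,
                 g2_ins + g[brows, 2] * (1 - g2_ins))
  for (q in seq_along(brows)) rv_dofs[brows[q], 1, ] <- bpos[q, ]
  dofs <- array(0, c(n_lv + nrow(idx), 8L, 3L))
  dofs[seq_len(n_lv), , ] <- lv$dofs
  dofs[n_lv + seq_len(nrow(idx)), , ] <- rv_dofs
  # RV elements
  rv_elems <- matrix(0L, m_c * m_l, 8L)
  e <- 0L
  for (jl in seq_len(m_l)) for (ic in seq_len(m_c)) {
    e <- e + 1L
    corners <- integer(8)
    for (cn in 1:8)
      corners[cn] <- rv_id(ic - 1L + .CORNER_I1[cn],
                           jl - 1L + .CORNER_I2[cn], .CORNER_I3[cn])
    rv_elems[e, ] <- corners
  }
  elements <- rbind(lv$elements, rv_elems)
  ne_lv <- nrow(lv$elements)
  rv_eid <- function(ic, jl) ne_lv + ic + m_c * (jl - 1L)
  faces <- lv$surface_faces
  names(faces)[names(faces) == "endo"] <- "endo_LV"
  rv_all <- as.matrix(expand.grid(ic = seq_len(m_c), jl = seq_len(m_l)))
  faces$endo_RV <- cbind(element = rv_eid(rv_all[, 1], rv_all[, 2]),
                         face = 5L)
  faces$epi <- rbind(faces$epi,
                     cbind(element = rv_eid(rv_all[, 1], rv_all[, 2]),
                           face = 6L))
  faces$base <- rbind(faces$base,
                      cbind(element = rv_eid(seq_len(m_c), m_l), face = 4L))
  # ties: insertion-line columns <-> LV epicardial nodes
  ties <- lv$tie_groups
  lv_epi_node <- function(is, it) {
    ic_global <- (((-(m_c %/% 2) + is) %% nc) + nc) %% nc + 1L
    .lv_node_id(ic_global, j_ins + it, nr, nc, nl)
  }
  for (q in which(on_boundary & idx$k == 0L)) {
    is <- idx$is[q]; it <- idx$it[q]
    ties[[length(ties) + 1L]] <-
      c(rv_id(is, it, 0L), rv_id(is, it, 1L), lv_epi_node(is, it))
  }
  m <- hermite_mesh(dofs, elements, topology = "BiV",
                    resolution = spec$resolution,
                    apex_style = spec$apex_style,
                    surface_faces = faces, tie_groups = ties,
                    regions = c(rep("LV", ne_lv), rep("RV", nrow(rv_elems))))
  cols <- lv$transmural_columns
  for (it in 0:m_l) for (is in 0:m_c)
    cols[[length(cols) + 1L]] <- c(rv_id(is, it, 0L), rv_id(is, it, 1L))
  m$transmural_columns <- cols
  m
}

#' Synthesize a template of either topology
#' @param spec a [template_spec()].
#' @return a [hermite_mesh()].
#' @export
synthesize_template <- function(spec) {
  if (identical(spec$topology, "BiV")) synthesize_biv(spec)
  else synthesize_lv(spec)
}

#' Analytic volume of a truncated ellipsoidal shell
#'
#' Closed-form volume of the solid bounded by an outer ellipsoid, an inner
#' ellipsoid (semi-axes reduced by the wall thickness) and the plane
#' `z = base_height`. Used as an independent oracle for quadrature volumes
#' and phantom voxel counts.
#'
#' @param outer_radii outer semi-axes (mm).
#' @param thickness wall thickness (mm).
#' @param base_height truncation plane height above the centre (mm).
#' @return volume in mm^3.
#' @export
truncated_shell_volume <- function(outer_radii, thickness, base_height) {
  tr_ell <- function(a, b, c, zb) {
    zb <- min(zb, c)
    pi * a * b * ((zb + c) - (zb^3 + c^3) / (3 * c^2))
  }
  tr_ell(outer_radii[1], outer_radii[2], outer_radii[3], base_height) -
    tr_ell(outer_radii[1] - thickness, outer_radii[2] - thickness,
           outer_radii[3] - thickness, base_height)
}

# Analytic descriptor of the template cavity in its canonical frame:
# moments of the solid truncated inner ellipsoid by 1-D Simpson integration.
.template_descriptor <- function(spec) {
  a <- spec$lv_outer_radii[1] - spec$lv_wall_thickness
  b <- spec$lv_outer_radii[2] - spec$lv_wall_thickness
  cc <- spec$lv_outer_radii[3] - spec$lv_wall_thickness
  zb <- spec$base_height
  z <- seq(-cc, zb, length.out = 801)
  u <- pmax(1 - z^2 / cc^2, 0)
  area <- pi * a * b * u
  simpson <- function(f) {
    h <- z[2] - z[1]
    n <- length(f)
    h / 3 * sum(f * c(1, rep(c(4, 2), length.out = n - 2), 1))
  }
  m0 <- simpson(area)
  zbar <- simpson(z * area) / m0
  var_z <- simpson(z^2 * area) / m0 - zbar^2
  var_x <- simpson((a^2 * u / 4) * area) / m0
  var_y <- simpson((b^2 * u / 4) * area) / m0
  sizes <- sqrt(5) * sqrt(c(var_x, var_y, var_z))
  list(
    axis_long = c(0, 0, 1), axis_lr = c(1, 0, 0), axis_third = c(0, 1, 0),
    basal_plane = list(point = c(0, 0, zb), normal = c(0, 0, 1)),
    lv_centroid = c(0, 0, zbar),
    lv_size = sizes, scaling = sizes,
    wall_thickness = spec$lv_wall_thickness,
    lv_extent_long = spec$lv_outer_radii[3] + zb,
    equator_offset = zb,
    topology = spec$topology
  )
}

#' Tailor a template spec to measured shape parameters
#'
#' Copies the LV cavity radii, wall thickness, base height and (for BiV) the
#' RV size, insertion level and angular span from a [shape
#' descriptor][analyze_shape()] into a template specification, so the
#' synthesized template is geometrically close to the target anatomy before
#' registration.
#'
#' @param descriptor a shape descriptor from [analyze_shape()] /
#'   [measure_dimensions()].
#' @param base_spec template spec supplying topology, resolution and other
#'   non-measured choices.
#' @return a [template_spec()].
#' @export
tailor_template <- function(descriptor, base_spec) {
  t <- descriptor$wall_thickness
  if (identical(base_spec$topology, "BiV") && is.null(descriptor$rv_size))
    stop("descriptor has no RV fields but topology is BiV")
  a_out <- descriptor$lv_size[1] + t
  b_out <- descriptor$lv_size[2] + t
  L <- descriptor$lv_extent_long
  h_eq <- descriptor$equator_offset
  c_out <- L - h_eq
  # keep the base plane safely below the inner apex
  c_in <- c_out - t
  if (h_eq >= 0.8 * c_in) {
    h_eq <- 0.8 * c_in
    c_out <- L - h_eq
    c_in <- c_out - t
  }
  args <- list(
    topology = base_spec$topology, resolution = base_spec$resolution,
    apex_style = base_spec$apex_style,
    lv_outer_radii = c(a_out, b_out, c_out),
    lv_wall_thickness = t, base_height = h_eq,
    truncate_base = base_spec$truncate_base,
    basal_offset = base_spec$basal_offset
  )
  if (identical(base_spec$topology, "BiV")) {
    tau <- max(0.35 * t, 1.5)
    args$rv_wall_thickness <- tau
    # clamp the RV length to the measurable LV extent (sparse stacks can
    # overestimate the RV pool extent by up to an interslice gap)
    rv_len <- min(descriptor$rv_extent[3], 0.9 * (c_out + h_eq))
    args$rv_size <- c(max(descriptor$rv_extent[1] + tau, 3 * tau),
                      descriptor$rv_extent[2],
                      rv_len)
    args$rv_insertion_level <-
      max(0.2, min(0.95, descriptor$rv_insertion_level))
    if (!is.null(descriptor$rv_angle)) args$rv_angle <- descriptor$rv_angle
  }
  do.call(template_spec, args)
}
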