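# Structured 8-node serendipity quadrilateral meshing of the corneal band.
#
# The mesh is a tensor grid in (meridional angle, normal depth): columns are
# meridional stations of the anterior arc, rows are through-thickness bands
# whose boundaries follow the layer interfaces and the tunnel footprint.  All
# lattice nodes (corners and midsides) are placed by the exact geometric
# mapping, so midside nodes on the anterior/posterior surfaces lie on the
# true arcs.

#' Mesh density controls
#'
#' Element counts for the structured corneal mesh: along the surface the
#' half-meridian is split into apex-to-tunnel, tunnel and tunnel-to-limbus
#' regions; through the thickness into epithelium, anterior stroma, posterior
#' stroma above the tunnel band, the 30-um tunnel band itself (always one
#' element), and posterior stroma below it.  The defaults give 64 x 6 = 384
#' elements in the axisymmetric half-section, matching the element budget of
#' a coarse structural mesh of this cross-section.
#'
#' @param n_inner elements from apex to the tunnel's inner edge.
#' @param n_tunnel elements across the tunnel footprint.
#' @param n_outer elements from the tunnel's outer edge to the limbus.
#' @param n_epithelium,n_anterior,n_post_above,n_post_below through-thickness
#'   element counts per band.
#' @param refine integer factor applied to every count (mesh-convergence
#'   studies).
#' @return object of class `mesh_density`.
#' @export
mesh_density <- function(n_inner = 26, n_tunnel = 8, n_outer = 30,
                         n_epithelium = 1, n_anterior = 2,
                         n_post_above = 1, n_post_below = 1,
                         refine = 1) {
  d <- list(n_inner = n_inner * refine, n_tunnel = n_tunnel * refine,
            n_outer = n_outer * refine, n_epithelium = n_epithelium * refine,
            n_anterior = n_anterior * refine,
            n_post_above = n_post_above * refine,
            n_post_below = n_post_below * refine)
  stopifnot(all(unlist(d) >= 1))
  structure(d, class = "mesh_density")
}

# quad-8 connectivity for one cell of a lattice id map: corners CCW starting
# at (i0, j1) = (left, posterior), then midsides 5..8 between 1-2, 2-3, 3-4,
# 4-1.  i indexes the meridional station (x-like), j the depth level
# (anterior = low j).
cell_connectivity <- function(idmap, i0, j0) {
  i1 <- i0 + 2; j1 <- j0 + 2
  c(idmap[i0, j1], idmap[i1, j1], idmap[i1, j0], idmap[i0, j0],
    idmap[i0 + 1, j1], idmap[i1, j0 + 1], idmap[i0 + 1, j0],
    idmap[i0, j0 + 1])
}

# Core structured band mesher over alpha station values and a per-station
# depth-level function.  Returns nodes, elements and lattice bookkeeping.
structured_band_mesh <- function(alpha_st, depth_fun, point_fun,
                                 row_labels) {
  ni <- length(alpha_st)
  nlev <- length(depth_fun(alpha_st[1]))
  depths <- vapply(alpha_st, depth_fun, numeric(nlev))
  nj <- nrow(depths)
  stopifnot(ni %% 2 == 1, nj %% 2 == 1)
  keep <- outer(seq_len(ni) %% 2 == 0, seq_len(nj) %% 2 == 0, `&`)
  keep <- !keep  # drop (odd i, odd j) biquadratic centre nodes (1-based!)
  # note: 1-based indices -> lattice parity: interior centre has even i & even j
  idmap <- matrix(NA_integer_, ni, nj)
  idmap[keep] <- seq_len(sum(keep))
  n_nodes <- sum(keep)
  nodes <- matrix(NA_real_, n_nodes, 2)
  node_alpha <- numeric(n_nodes)
  node_depth <- numeric(n_nodes)
  node_i <- integer(n_nodes); node_j <- integer(n_nodes)
  for (i in seq_len(ni)) for (j in seq_len(nj)) {
    id <- idmap[i, j]
    if (is.na(id)) next
    nodes[id, ] <- point_fun(alpha_st[i], depths[j, i])
    node_alpha[id] <- alpha_st[i]
    node_depth[id] <- depths[j, i]
    node_i[id] <- i; node_j[id] <- j
  }
  ncol_el <- (ni - 1) / 2
  nrow_el <- (nj - 1) / 2
  elements <- matrix(NA_integer_, ncol_el * nrow_el, 8)
  el_col <- integer(ncol_el * nrow_el)
  el_row <- integer(ncol_el * nrow_el)
  e <- 0L
  for (k in seq_len(ncol_el)) for (r in seq_len(nrow_el)) {
    e <- e + 1L
    elements[e, ] <- cell_connectivity(idmap, 2 * k - 1, 2 * r - 1)
    el_col[e] <- k; el_row[e] <- r
  }
  list(nodes = nodes, elements = elements, idmap = idmap,
       node_alpha = node_alpha, node_depth = node_depth,
       node_i = node_i, node_j = node_j,
       el_col = el_col, el_row = el_row,
       ncol_el = ncol_el, nrow_el = nrow_el,
       row_labels = row_labels, alpha_st = alpha_st, depths = depths)
}

# station values (corner + midside) from region break points and counts
stations_from_breaks <- function(breaks, counts) {
  st <- breaks[1]
  for (k in seq_along(counts)) {
    seg <- seq(breaks[k], breaks[k + 1], length.out = 2 * counts[k] + 1)
    st <- c(st, seg[-1])
  }
  st
}

#' Generate the structured corneal mesh
#'
#' Meshes the layered corneal cross-section with 8-node quadrilaterals.  The
#' tunnel footprint is resolved by a dedicated block of elements tagged in
#' `element_sets$tunnel`, whose boundary nodes form `node_sets$tunnel_boundary`.
#' In the axisymmetric mode the half-meridian (x >= 0) is meshed; in plane
#' strain the full section, with the tunnel on the positive-x side only.
#'
#' @param geometry a [cornea_geometry()].
#' @param tunnel a [tunnel_spec()].
#' @param density a [mesh_density()].
#' @param mode `"axisymmetric"` or `"plane_strain"`.
#' @return object of class `cornea_mesh` with fields `nodes` (mm), `elements`
#'   (quad-8 connectivity), `elem_material`, `element_sets`, `node_sets`,
#'   `edge_sets` (oriented boundary edge chains), `active` and bookkeeping.
#' @export
generate_mesh <- function(geometry, tunnel = tunnel_spec(),
                          density = mesh_density(),
                          mode = c("axisymmetric", "plane_strain")) {
  mode <- match.arg(mode)
  validate_tunnel(geometry, tunnel)
  am <- alpha_max(geometry)
  a_c <- tunnel_center_alpha(geometry, tunnel)
  tot_c <- normal_depth_to_posterior(geometry, a_c)
  d_mid <- tunnel$depth_fraction * tot_c + 0.5 * tunnel$height / UM_PER_MM
  da <- (tunnel$width / UM_PER_MM / 2) / (geometry$r_anterior - d_mid)
  a_lo <- a_c - da; a_hi <- a_c + da
  if (a_lo <= 0 || a_hi >= am)
    stop("tunnel footprint does not fit between apex and limbus")
  breaks <- c(0, a_lo, a_hi, am)
  counts <- c(density$n_inner, density$n_tunnel, density$n_outer)
  tun_cols <- density$n_inner + seq_len(density$n_tunnel)
  if (mode == "plane_strain") {
    breaks <- c(-rev(breaks[-1]), breaks)
    counts <- c(rev(counts), counts)
    tun_cols <- sum(counts[1:4]) + seq_len(density$n_tunnel)
  }
  alpha_st <- stations_from_breaks(breaks, counts)

  rc <- c(density$n_epithelium, density$n_anterior, density$n_post_above,
          1L, density$n_post_below)
  row_band <- rep(c("epithelium", "anterior_stroma", "posterior_above",
                    "tunnel_band", "posterior_below"), rc)
  row_mat <- rep(c("epithelium", "anterior_stroma", "posterior_stroma",
                   "posterior_stroma", "posterior_stroma"), rc)
  depth_fun <- function(a) {
    ld <- layer_depths(geometry, a)
    d0 <- tunnel$depth_fraction * ld[["posterior"]]
    d1 <- d0 + tunnel$height / UM_PER_MM
    bks <- c(0, ld[["epi"]], ld[["stroma_split"]], d0, d1, ld[["posterior"]])
    stations_from_breaks(bks, rc)
  }
  point_fun <- function(a, d) point_at_depth(geometry, a, d)[1, ]
  bm <- structured_band_mesh(alpha_st, depth_fun, point_fun, row_band)

  ne <- nrow(bm$elements)
  elem_material <- row_mat[bm$el_row]
  tun_row <- which(row_band == "tunnel_band")
  tunnel_el <- which(bm$el_row == tun_row & bm$el_col %in% tun_cols)
  element_sets <- list(
    epithelium = which(elem_material == "epithelium"),
    anterior_stroma = which(elem_material == "anterior_stroma"),
    posterior_stroma = setdiff(which(elem_material == "posterior_stroma"),
                               tunnel_el),
    tunnel = tunnel_el)

  ni <- length(alpha_st); nj <- nrow(bm$depths)
  anterior_nodes <- bm$idmap[, 1][!is.na(bm$idmap[, 1])]
  posterior_nodes <- bm$idmap[, nj][!is.na(bm$idmap[, nj])]
  limbus_nodes <- bm$idmap[ni, ][!is.na(bm$idmap[ni, ])]
  if (mode == "plane_strain")
    limbus_nodes <- c(bm$idmap[1, ][!is.na(bm$idmap[1, ])], limbus_nodes)
  node_sets <- list(anterior_surface = unname(anterior_nodes),
                    posterior_surface = unname(posterior_nodes),
                    limbus = unname(limbus_nodes))
  if (mode == "axisymmetric")
    node_sets$apex_axis <- unname(bm$idmap[1, ][!is.na(bm$idmap[1, ])])

  tun_nodes <- sort(unique(as.integer(bm$elements[tunnel_el, ])))
  other_nodes <- sort(unique(as.integer(bm$elements[-tunnel_el, ])))
  node_sets$tunnel <- tun_nodes
  node_sets$tunnel_boundary <- intersect(tun_nodes, other_nodes)
  node_sets$tunnel_interior <- setdiff(tun_nodes, other_nodes)

  # oriented boundary edge chains (CCW around the domain): posterior surface
  # traversed in +alpha, anterior in -alpha, so outward normal = (t_y, -t_x)
  bot <- which(bm$el_row == bm$nrow_el)
  bot <- bot[order(bm$el_col[bot])]
  post_edges <- bm$elements[bot, c(1, 5, 2), drop = FALSE]
  top <- which(bm$el_row == 1L)
  top <- top[order(bm$el_col[top], decreasing = TRUE)]
  ant_edges <- bm$elements[top, c(3, 7, 4), drop = FALSE]
  edge_sets <- list(posterior_surface = post_edges,
                    anterior_surface = ant_edges)

  mesh <- structure(
    list(nodes = bm$nodes, elements = bm$elements,
         elem_material = elem_material, element_sets = element_sets,
         node_sets = node_sets, edge_sets = edge_sets,
         active = rep(TRUE, ne), mode = mode,
         material_axes = list(type = "spherical",
                              center = c(0, -geometry$r_anterior)),
         geometry = geometry, tunnel = tunnel, density = density,
         node_alpha = bm$node_alpha, node_depth = bm$node_depth,
         el_col = bm$el_col, el_row = bm$el_row),
    class = "cornea_mesh")
  check_jacobians(mesh)
  mesh
}

#' @export
print.cornea_mesh <- function(x, ...) {
  cat(sprintf("<cornea_mesh> %d nodes, %d elements (%d active), mode %s\n",
              nrow(x$nodes), nrow(x$elements), sum(x$active), x$mode))
  cat(sprintf("  sets: %s\n", paste(names(x$element_sets), collapse = ", ")))
  invisible(x)
}

#' Deactivate the tunnel elements
#'
#' Returns a copy of the mesh in which the elements of the tunnel block are
#' inactive (excluded from assembly), representing the carved stromal tunnel.
#' The pre-operative cornea uses the uncarved mesh; implantation uses the
#' carved one.  Carving an already carved mesh warns and is a no-op.
#'
#' @param mesh a [generate_mesh()] result with a tunnel element set.
#' @return the carved mesh.
#' @export
carve_tunnel <- function(mesh) {
  tun <- mesh$element_sets$tunnel
  if (length(tun) == 0) stop("mesh has no tunnel element set")
  if (all(!mesh$active[tun])) {
    warning("tunnel already carved; returning mesh unchanged")
    return(mesh)
  }
  mesh$active[tun] <- FALSE
  mesh
}

# minimum Jacobian determinant over 3x3 Gauss points of every element
check_jacobians <- function(mesh) {
  gp <- gauss_2d(3)
  for (e in seq_len(nrow(mesh$elements))) {
    xy <- mesh$nodes[mesh$elements[e, ], ]
    for (g in seq_len(nrow(gp$pts))) {
      dN <- quad8_shape(gp$pts[g, 1], gp$pts[g, 2])$dN
      J <- t(dN) %*% xy
      if (det(J) <= 0)
        stop(sprintf("element %d has non-positive Jacobian", e))
    }
  }
  invisible(TRUE)
}

#' Total meshed area
#'
#' Cross-sectional area (mm^2) of the mesh by Gauss integration of the
#' Jacobian, optionally restricted to active elements.
#'
#' @param mesh a `cornea_mesh`.
#' @param active_only integrate only active elements.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh, active_only = FALSE) {
  gp <- gauss_2d(3)
  els <- seq_len(nrow(mesh$elements))
  if (active_only) els <- els[mesh$active]
  area <- 0
  for (e in els) {
    xy <- mesh$nodes[mesh$elements[e, ], ]
    for (g in seq_len(nrow(gp$pts))) {
      dN <- quad8_shape(gp$pts[g, 1], gp$pts[g, 2])$dN
      area <- area + gp$w[g] * det(t(dN) %*% xy)
    }
  }
  area
}

#' Structured rectangular quad-8 mesh
#'
#' Utility mesh over `[x0, x0+width] x [y0, y0+height]` used for verification
#' problems (patch tests, closed-form oracles).  Interior corner nodes can be
#' perturbed (`distort`) to exercise non-rectangular element shapes; midside
#' nodes are re-placed at edge midpoints so edges stay straight.
#'
#' @param nx,ny element counts.
#' @param width,height extents in mm.
#' @param x0,y0 lower-left corner, mm.
#' @param material single material label applied to all elements.
#' @param distort fraction of the cell size by which interior corner nodes
#'   are shifted (deterministic pattern).
#' @return a `cornea_mesh`-compatible object with node sets `left`, `right`,
#'   `bottom`, `top` and matching oriented edge sets.
#' @export
mesh_rectangle <- function(nx, ny, width, height, x0 = 0, y0 = 0,
                           material = "mat", distort = 0) {
  xs <- seq(x0, x0 + width, length.out = 2 * nx + 1)
  ys <- seq(y0, y0 + height, length.out = 2 * ny + 1)
  ni <- length(xs); nj <- length(ys)
  # lattice coordinates; j = 1 is the top (anterior-like) row to reuse the
  # band connectivity (corners 1-2 on the high-j = bottom side)
  coords <- function(i, j) c(xs[i], ys[nj - j + 1])
  keep <- !outer(seq_len(ni) %% 2 == 0, seq_len(nj) %% 2 == 0, `&`)
  idmap <- matrix(NA_integer_, ni, nj)
  idmap[keep] <- seq_len(sum(keep))
  nodes <- matrix(NA_real_, sum(keep), 2)
  for (i in seq_len(ni)) for (j in seq_len(nj))
    if (!is.na(idmap[i, j])) nodes[idmap[i, j], ] <- coords(i, j)
  if (distort > 0) {
    dx <- width / nx * distort; dy <- height / ny * distort
    for (i in seq(3, ni - 2, by = 2)) for (j in seq(3, nj - 2, by = 2)) {
      id <- idmap[i, j]
      s <- if (((i + j) / 2) %% 2 == 0) 1 else -1
      nodes[id, ] <- nodes[id, ] + c(dx, -dy) * s
    }
    # midside nodes back to edge midpoints
    for (i in seq_len(ni)) for (j in seq_len(nj)) {
      if (is.na(idmap[i, j])) next
      if (i %% 2 == 0 && j %% 2 == 1)   # horizontal-edge midside
        nodes[idmap[i, j], ] <-
          (nodes[idmap[i - 1, j], ] + nodes[idmap[i + 1, j], ]) / 2
      if (i %% 2 == 1 && j %% 2 == 0)   # vertical-edge midside
        nodes[idmap[i, j], ] <-
          (nodes[idmap[i, j - 1], ] + nodes[idmap[i, j + 1], ]) / 2
    }
  }
  ne <- nx * ny
  elements <- matrix(NA_integer_, ne, 8)
  el_col <- integer(ne); el_row <- integer(ne)
  e <- 0L
  for (k in seq_len(nx)) for (r in seq_len(ny)) {
    e <- e + 1L
    elements[e, ] <- cell_connectivity(idmap, 2 * k - 1, 2 * r - 1)
    el_col[e] <- k; el_row[e] <- r
  }
  node_sets <- list(
    left = unname(idmap[1, ][!is.na(idmap[1, ])]),
    right = unname(idmap[ni, ][!is.na(idmap[ni, ])]),
    top = unname(idmap[, 1][!is.na(idmap[, 1])]),
    bottom = unname(idmap[, nj][!is.na(idmap[, nj])]))
  # oriented CCW edge chains: bottom (+x), right (+y), top (-x), left (-y)
  bot_el <- order(el_col[el_row == ny]); bot_ids <- which(el_row == ny)[bot_el]
  top_el <- order(el_col[el_row == 1], decreasing = TRUE)
  top_ids <- which(el_row == 1)[top_el]
  right_ids <- which(el_col == nx)[order(el_row[el_col == nx],
                                         decreasing = TRUE)]
  left_ids <- which(el_col == 1)[order(el_row[el_col == 1])]
  edge_sets <- list(
    bottom = elements[bot_ids, c(1, 5, 2), drop = FALSE],
    right = elements[right_ids, c(2, 6, 3), drop = FALSE],
    top = elements[top_ids, c(3, 7, 4), drop = FALSE],
    left = elements[left_ids, c(4, 8, 1), drop = FALSE])
  structure(
    list(nodes = nodes, elements = elements,
         elem_material = rep(material, ne),
         element_sets = stats::setNames(list(seq_len(ne)), material),
         node_sets = node_sets, edge_sets = edge_sets,
         active = rep(TRUE, ne), mode = "plane_strain",
         material_axes = list(type = "cartesian", angle = pi / 2),
         geometry = NULL, tunnel = NULL, density = NULL,
         el_col = el_col, el_row = el_row),
    class = "cornea_mesh")
}

#' Structured quad-8 mesh of a concentric spherical/cylindrical shell section
#'
#' Meshes the band between two concentric arcs of radii `r_inner` and
#' `r_outer` (centre at the origin) over meridional angles `[0, alpha_span]`
#' from the +y axis.  Used for Lame thick-shell verification problems.
#'
#' @param r_inner,r_outer shell radii, mm.
#' @param n_merid,n_thick element counts.
#' @param alpha_span meridional extent in radians (default `pi/2`, a quarter
#'   section from pole to equator).
#' @param material material label.
#' @return a `cornea_mesh`-compatible object with node sets `inner`, `outer`,
#'   `axis`, `equator` and oriented edge sets `inner`, `outer`.
#' @export
mesh_shell <- function(r_inner, r_outer, n_merid = 12, n_thick = 3,
                       alpha_span = pi / 2, material = "mat") {
  stopifnot(r_outer > r_inner, r_inner > 0)
  alpha_st <- seq(0, alpha_span, length.out = 2 * n_merid + 1)
  depth_fun <- function(a) seq(0, r_outer - r_inner,
                               length.out = 2 * n_thick + 1)
  point_fun <- function(a, d) c((r_outer - d) * sin(a), (r_outer - d) * cos(a))
  bm <- structured_band_mesh(alpha_st, depth_fun, point_fun,
                             rep(material, n_thick))
  ne <- nrow(bm$elements)
  nj <- nrow(bm$depths); ni <- length(alpha_st)
  node_sets <- list(
    outer = unname(bm$idmap[, 1][!is.na(bm$idmap[, 1])]),
    inner = unname(bm$idmap[, nj][!is.na(bm$idmap[, nj])]),
    axis = unname(bm$idmap[1, ][!is.na(bm$idmap[1, ])]),
    equator = unname(bm$idmap[ni, ][!is.na(bm$idmap[ni, ])]))
  bot <- which(bm$el_row == bm$nrow_el); bot <- bot[order(bm$el_col[bot])]
  top <- which(bm$el_row == 1L)
  top <- top[order(bm$el_col[top], decreasing = TRUE)]
  edge_sets <- list(inner = bm$elements[bot, c(1, 5, 2), drop = FALSE],
                    outer = bm$elements[top, c(3, 7, 4), drop = FALSE])
  structure(
    list(nodes = bm$nodes, elements = bm$elements,
         elem_material = rep(material, ne),
         element_sets = stats::setNames(list(seq_len(ne)), material),
         node_sets = node_sets, edge_sets = edge_sets,
         active = rep(TRUE, ne), mode = "axisymmetric",
         material_axes = list(type = "spherical", center = c(0, 0)),
         geometry = NULL, tunnel = NULL, density = NULL,
         el_col = bm$el_col, el_row = bm$el_row),
    class = "cornea_mesh")
}

#' Export a mesh (optionally with fields) as legacy ASCII VTK
#'
#' Writes an unstructured-grid file with quad-8 cells (VTK type 23) for
#' visual inspection.  Optional per-node displacements and a per-element
#' scalar (e.g. von Mises stress) are attached as data arrays.
#'
#' @param mesh a `cornea_mesh`.
#' @param path output file path.
#' @param displacements optional n_nodes x 2 matrix (mm).
#' @param cell_scalar optional named list with one numeric vector per active
#'   element.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, displacements = NULL, cell_scalar = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  els <- which(mesh$active)
  nn <- nrow(mesh$nodes)
  xy <- mesh$nodes
  if (!is.null(displacements)) xy <- xy + displacements
  writeLines(c("# vtk DataFile Version 3.0", "corneafem mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  writeLines(sprintf("%.9g %.9g 0", xy[, 1], xy[, 2]), con)
  writeLines(sprintf("CELLS %d %d", length(els), 9 * length(els)), con)
  writeLines(apply(mesh$elements[els, , drop = FALSE] - 1L, 1,
                   function(r) paste(c(8, r), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", length(els)), con)
  writeLines(rep("23", length(els)), con)
  if (!is.null(cell_scalar)) {
    writeLines(sprintf("CELL_DATA %d", length(els)), con)
    for (nm in names(cell_scalar)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", cell_scalar[[nm]]), con)
    }
  }
  invisible(path)
}
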