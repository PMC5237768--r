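#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort
NULL

# ---- low-level mesh container -----------------------------------------------

#' Construct a 2D quadrilateral mesh
#'
#' Low-level constructor used by the domain generators. Coordinates are in
#' cm; element areas are computed by the shoelace formula and validated to
#' be strictly positive with counter-clockwise node ordering.
#'
#' @param nodes Data frame with columns `x`, `y` (cm), one row per node.
#' @param elements Data frame with integer columns `n1`..`n4` (node indices,
#'   counter-clockwise) and optionally a `region` column.
#' @param node_sets Named list of integer node-index vectors (boundary and
#'   load groups).
#' @param element_sets Named list of integer element-index vectors (regions);
#'   the sets must partition the elements.
#' @param fixed_set Name of the node set clamped in elasticity solves.
#' @return An object of class `bone_mesh`: a list with `nodes`, `elements`,
#'   `element_area` (cm2), `node_sets`, `element_sets` and a `fixed_set`
#'   attribute.
#' @export
bone_mesh <- function(nodes, elements, node_sets = list(),
                      element_sets = list(), fixed_set = NULL) {
  nodes <- as_tibble(nodes)
  elements <- as_tibble(elements)
  stopifnot(all(c("x", "y") %in% names(nodes)),
            all(c("n1", "n2", "n3", "n4") %in% names(elements)))
  conn <- as.matrix(elements[, c("n1", "n2", "n3", "n4")])
  storage.mode(conn) <- "integer"
  n_nodes <- nrow(nodes)
  if (any(conn < 1L) || any(conn > n_nodes)) {
    abort("element connectivity references node indices out of range")
  }
  if (any(apply(conn, 1L, anyDuplicated) > 0L)) {
    abort("element with repeated node indices")
  }
  # signed shoelace area; must be positive (counter-clockwise, not inverted)
  xs <- matrix(nodes$x[conn], ncol = 4L)
  ys <- matrix(nodes$y[conn], ncol = 4L)
  nxt <- c(2L, 3L, 4L, 1L)
  area <- 0.5 * rowSums(xs * ys[, nxt] - xs[, nxt] * ys)
  if (any(area <= 0)) {
    abort(sprintf("element %d has non-positive area (inverted or degenerate)",
                  which(area <= 0)[1L]))
  }
  for (s in names(node_sets)) {
    idx <- node_sets[[s]]
    if (length(idx) && (any(idx < 1L) || any(idx > n_nodes))) {
      abort(sprintf("node set '%s' references nodes out of range", s))
    }
  }
  mesh <- structure(
    list(
      nodes = nodes,
      elements = elements,
      element_area = area,
      node_sets = node_sets,
      element_sets = element_sets,
      fixed_set = fixed_set,
      cache = new.env(parent = emptyenv())
    ),
    class = "bone_mesh"
  )
  mesh
}

#' @export
print.bone_mesh <- function(x, ...) {
  cat(sprintf("<bone_mesh> %d nodes, %d elements, total area %.4g cm2\n",
              nrow(x$nodes), nrow(x$elements), sum(x$element_area)))
  if (length(x$element_sets)) {
    sizes <- vapply(x$element_sets, length, integer(1))
    cat("  element sets:", paste(sprintf("%s (%d)", names(sizes), sizes),
                                 collapse = ", "), "\n")
  }
  if (length(x$node_sets)) {
    sizes <- vapply(x$node_sets, length, integer(1))
    cat("  node sets   :", paste(sprintf("%s (%d)", names(sizes), sizes),
                                 collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of elements / nodes in a mesh
#' @param mesh A [bone_mesh()].
#' @return Integer count.
#' @export
n_elements <- function(mesh) nrow(mesh$elements)

#' @rdname n_elements
#' @export
n_nodes <- function(mesh) nrow(mesh$nodes)

# structured grid over a rectangular lattice with a cell keep-mask
build_structured_mesh <- function(origin, elem, nx, ny, keep = NULL) {
  dx <- elem[1L]
  dy <- if (length(elem) > 1L) elem[2L] else elem[1L]
  if (is.null(keep)) keep <- matrix(TRUE, nx, ny)
  stopifnot(nrow(keep) == nx, ncol(keep) == ny)
  fid <- function(i, j) (j - 1L) * (nx + 1L) + i
  cells <- which(keep, arr.ind = TRUE)
  if (nrow(cells) == 0L) abort("keep mask retains no cells")
  ci <- cells[, 1L]; cj <- cells[, 2L]
  conn_full <- cbind(fid(ci, cj), fid(ci + 1L, cj),
                     fid(ci + 1L, cj + 1L), fid(ci, cj + 1L))
  used <- sort(unique(as.vector(conn_full)))
  remap <- integer((nx + 1L) * (ny + 1L))
  remap[used] <- seq_along(used)
  gi <- (used - 1L) %% (nx + 1L) + 1L
  gj <- (used - 1L) %/% (nx + 1L) + 1L
  nodes <- tibble(
    x = origin[1L] + (gi - 1L) * dx,
    y = origin[2L] + (gj - 1L) * dy
  )
  elements <- tibble(
    n1 = remap[conn_full[, 1L]], n2 = remap[conn_full[, 2L]],
    n3 = remap[conn_full[, 3L]], n4 = remap[conn_full[, 4L]],
    cell_i = as.integer(ci), cell_j = as.integer(cj)
  )
  list(nodes = nodes, elements = elements, dx = dx, dy = dy)
}

# indices of the k nodes nearest to a target point
nodes_nearest <- function(nodes, point, k) {
  d2 <- (nodes$x - point[1L])^2 + (nodes$y - point[2L])^2
  order(d2)[seq_len(k)]
}

# ---- plate fixture ----------------------------------------------------------

plate_domain_defaults <- function() {
  list(elem_cm = 0.5)
}

#' Rectangular plate test mesh
#'
#' Structured `nx` by `ny` quadrilateral plate with a clamped left edge
#' (`left`) and a load node set on the right edge (`right`). Used as a
#' fixture for solver verification and toy remodeling problems.
#'
#' @param nx,ny Number of elements along x and y (>= 1).
#' @param elem_cm Element edge length (cm).
#' @return A [bone_mesh()] with all elements in set `body`.
#' @export
#' @examples
#' generate_plate_fixture(2, 2)
generate_plate_fixture <- function(nx, ny, elem_cm = 0.5) {
  if (length(nx) != 1L || length(ny) != 1L || nx < 1 || ny < 1 ||
      nx != round(nx) || ny != round(ny)) {
    abort("`nx` and `ny` must be positive whole numbers")
  }
  nx <- as.integer(nx); ny <- as.integer(ny)
  g <- build_structured_mesh(c(0, 0), elem_cm, nx, ny)
  left <- which(g$nodes$x <= 1e-12)
  right <- which(g$nodes$x >= nx * elem_cm - 1e-12)
  bone_mesh(
    nodes = g$nodes,
    elements = dplyr::mutate(g$elements, region = "body"),
    node_sets = list(left = left, right = right),
    element_sets = list(body = seq_len(nrow(g$elements))),
    fixed_set = "left"
  )
}

# ---- femur-like domain ------------------------------------------------------

femur_domain_defaults <- function() {
  list(
    elem_cm = 0.5,
    shaft_x = c(3.5, 13.5),  # medial/lateral shaft walls (cm)
    shaft_top = 17,
    head_center = c(4.5, 22),
    head_radius = 5.4,
    neck_from = c(9, 14),
    neck_to = c(5.5, 19.5),
    neck_halfwidth = 3.8,
    troch_center = c(14, 16),
    troch_rx = 3.0,
    troch_ry = 3.8,
    troch_xmin = 12,
    cortical_layers = 1L,
    cortical_layers_shaft = 2L,
    defect_center = c(5.5, 9.5),
    defect_nx = 6L,
    defect_ny = 6L,
    n_load_nodes = 3L
  )
}

# squared distance from points to a segment
dist_to_segment <- function(px, py, a, b) {
  vx <- b[1L] - a[1L]; vy <- b[2L] - a[2L]
  tt <- ((px - a[1L]) * vx + (py - a[2L]) * vy) / (vx^2 + vy^2)
  tt <- pmin(1, pmax(0, tt))
  sqrt((px - (a[1L] + tt * vx))^2 + (py - (a[2L] + tt * vy))^2)
}

femur_mask <- function(cx, cy, p) {
  shaft <- cx >= p$shaft_x[1L] & cx <= p$shaft_x[2L] & cy <= p$shaft_top
  head <- (cx - p$head_center[1L])^2 + (cy - p$head_center[2L])^2 <=
    p$head_radius^2
  neck <- dist_to_segment(cx, cy, p$neck_from, p$neck_to) <= p$neck_halfwidth
  troch <- ((cx - p$troch_center[1L]) / p$troch_rx)^2 +
    ((cy - p$troch_center[2L]) / p$troch_ry)^2 <= 1 & cx >= p$troch_xmin
  shaft | head | neck | troch
}

# peel `layers` boundary layers off an occupancy mask; returns the layer
# index of each TRUE cell (1 = outermost), Inf for deeper cells
boundary_layers <- function(occ, layers) {
  nx <- nrow(occ); ny <- ncol(occ)
  depth <- matrix(Inf, nx, ny)
  current <- occ
  pad <- function(m, di, dj) {
    out <- matrix(FALSE, nx, ny)
    si <- seq_len(nx) + di; sj <- seq_len(ny) + dj
    ok_i <- si >= 1L & si <= nx; ok_j <- sj >= 1L & sj <= ny
    out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
    out
  }
  for (layer in seq_len(layers)) {
    nb_out <- !pad(current, 1L, 0L) | !pad(current, -1L, 0L) |
      !pad(current, 0L, 1L) | !pad(current, 0L, -1L)
    edge <- current & nb_out
    depth[edge & occ & !is.finite(depth)] <- layer
    current <- current & !edge
    if (!any(current)) break
  }
  depth
}

#' Parametric proximal-femur-like domain
#'
#' Generates a 2D stand-in for a proximal femur cross-section on a
#' structured grid of 0.5 cm square elements (0.25 cm2 each): a shaft,
#' femoral head, neck and greater trochanter, with a cortical shell one to
#' two element layers thick and a cancellous interior. A square defect of
#' `defect_nx * defect_ny` elements (default 6 x 6 = 36) straddles the
#' lateral cortex and the cancellous interior. The geometry is parametric,
#' not CT-derived, so absolute anatomy is schematic; the mesh statistics
#' (element size, element count, 36-element defect) match the reference
#' femur model.
#'
#' Node sets: `distal_fix` (clamped shaft base), `head_load` (femoral head
#' contact nodes), `troch_load` (greater trochanter muscle attachment).
#' Element sets: `cortical`, `cancellous`, `defect` (a partition).
#'
#' @param config A [remodel_config()]; the `femur` entry holds the domain
#'   parameters.
#' @return A [bone_mesh()].
#' @export
generate_femur_domain <- function(config = remodel_config()) {
  p <- config$femur
  h <- p$elem_cm
  xmax <- max(p$shaft_x[2L], p$troch_center[1L] + p$troch_rx,
              p$head_center[1L] + p$head_radius)
  ymax <- max(p$head_center[2L] + p$head_radius,
              p$troch_center[2L] + p$troch_ry)
  nx <- as.integer(ceiling(xmax / h))
  ny <- as.integer(ceiling(ymax / h))
  cx <- ((seq_len(nx) - 0.5) * h)
  cy <- ((seq_len(ny) - 0.5) * h)
  keep <- outer(cx, cy, function(a, b) femur_mask(a, b, p))
  g <- build_structured_mesh(c(0, 0), h, nx, ny, keep)
  elems <- g$elements
  ne <- nrow(elems)

  # cortical shell: outer boundary layer(s); thicker along the shaft
  occ <- keep
  depth <- boundary_layers(occ, max(p$cortical_layers, p$cortical_layers_shaft))
  ecx <- (elems$cell_i - 0.5) * h
  ecy <- (elems$cell_j - 0.5) * h
  edepth <- depth[cbind(elems$cell_i, elems$cell_j)]
  layers_here <- ifelse(ecy <= p$shaft_top, p$cortical_layers_shaft,
                        p$cortical_layers)
  cortical <- which(edepth <= layers_here)

  defect <- integer(0)
  if (p$defect_nx > 0L && p$defect_ny > 0L) {
    i0 <- as.integer(round((p$defect_center[1L] - p$defect_nx * h / 2) / h)) + 1L
    j0 <- as.integer(round((p$defect_center[2L] - p$defect_ny * h / 2) / h)) + 1L
    want_i <- i0:(i0 + p$defect_nx - 1L)
    want_j <- j0:(j0 + p$defect_ny - 1L)
    in_block <- elems$cell_i %in% want_i & elems$cell_j %in% want_j
    defect <- which(in_block)
    if (length(defect) != p$defect_nx * p$defect_ny) {
      abort(paste0("defect placement falls outside the femur domain: ",
                   "region 'defect' requires ", p$defect_nx * p$defect_ny,
                   " elements but only ", length(defect), " lie inside"))
    }
  }
  cortical <- setdiff(cortical, defect)
  cancellous <- setdiff(seq_len(ne), union(cortical, defect))

  region <- character(ne)
  region[cortical] <- "cortical"
  region[cancellous] <- "cancellous"
  region[defect] <- "defect"
  elems$region <- region

  distal <- which(g$nodes$y <= 1e-12)
  k <- p$n_load_nodes
  head_top <- p$head_center + c(0, p$head_radius)
  troch_top <- c(p$troch_center[1L], p$troch_center[2L] + p$troch_ry)
  bone_mesh(
    nodes = g$nodes,
    elements = elems,
    node_sets = list(
      distal_fix = distal,
      head_load = nodes_nearest(g$nodes, head_top, k),
      troch_load = nodes_nearest(g$nodes, troch_top, k)
    ),
    element_sets = list(
      cortical = cortical,
      cancellous = cancellous,
      defect = defect
    ),
    fixed_set = "distal_fix"
  )
}

# ---- rat metaphysis domain --------------------------------------------------

rat_domain_defaults <- function() {
  list(
    elem_cm = 0.05,          # 0.5 mm elements
    width = 0.8,             # cm (8 mm metaphysis cross-section)
    height = 1.0,            # cm
    cortex_layers = 2L,      # 1 mm cortical wall on medial/lateral sides
    metaphyseal_frac = 0.35, # upper fraction with the softer cortex
    defect = TRUE,
    defect_nx = 6L,          # 3 mm x 3 mm defect of 0.5 mm cells
    defect_ny = 6L,
    defect_center_y = 0.5,   # cm, on the lateral (right) cortex
    moduli = c(cortical_stiff = 7000, cortical_soft = 2000,
               cancellous = 900, implant = 800),
    load_frac = 1            # fraction of the top edge carrying the joint
  )                          # force (distributed across the growth plate)
}

#' Parametric rat-metaphysis domain
#'
#' 2D stand-in for the metaphysis of a rat femur: a rectangular
#' cross-section of 0.5 mm square elements with a two-part cortical wall
#' (stiff diaphyseal cortex, softer metaphyseal cortex near the growth
#' plate), cancellous interior, and a 3 mm x 3 mm drill defect on the
#' lateral cortex (36 elements, 9 mm2). Each region carries its in-vivo
#' elastic modulus (7000 / 2000 MPa cortex, 900 MPa cancellous, 800 MPa
#' calcium-sulfate implant), stored as `initial_modulus` per element;
#' `pre_defect_modulus` records what each defect element replaced.
#'
#' Node sets: `distal_fix` (clamped base), `joint_load` (central top edge,
#' where the joint force acts). Element sets: `cortical`, `cancellous`,
#' `defect` (a partition).
#'
#' @inheritParams generate_femur_domain
#' @return A [bone_mesh()] with `initial_modulus` and `pre_defect_modulus`
#'   fields.
#' @export
generate_rat_domain <- function(config = remodel_config()) {
  p <- config$rat
  h <- p$elem_cm
  nx <- as.integer(round(p$width / h))
  ny <- as.integer(round(p$height / h))
  g <- build_structured_mesh(c(0, 0), h, nx, ny)
  elems <- g$elements
  ne <- nrow(elems)

  lat_wall <- elems$cell_i > nx - p$cortex_layers
  med_wall <- elems$cell_i <= p$cortex_layers
  cortical <- which(lat_wall | med_wall)
  upper <- (elems$cell_j - 0.5) * h > p$height * (1 - p$metaphyseal_frac)
  subregion <- rep("cancellous", ne)
  subregion[cortical] <- ifelse(upper[cortical], "cortical_soft",
                                "cortical_stiff")
  pre_defect_modulus <- unname(p$moduli[subregion])

  defect <- integer(0)
  if (isTRUE(p$defect) && p$defect_nx > 0L && p$defect_ny > 0L) {
    want_i <- (nx - p$defect_nx + 1L):nx  # lateral edge inward
    j0 <- as.integer(round((p$defect_center_y - p$defect_ny * h / 2) / h)) + 1L
    want_j <- j0:(j0 + p$defect_ny - 1L)
    in_block <- elems$cell_i %in% want_i & elems$cell_j %in% want_j
    defect <- which(in_block)
    if (length(defect) != p$defect_nx * p$defect_ny) {
      abort(paste0("defect placement falls outside the rat domain: ",
                   "region 'defect' requires ", p$defect_nx * p$defect_ny,
                   " elements but only ", length(defect), " lie inside"))
    }
  }
  cortical <- setdiff(cortical, defect)
  cancellous <- setdiff(seq_len(ne), union(cortical, defect))

  region <- rep("cancellous", ne)
  region[cortical] <- "cortical"
  region[defect] <- "defect"
  elems$region <- region
  elems$subregion <- ifelse(region == "defect", "defect", subregion)

  initial_modulus <- pre_defect_modulus
  initial_modulus[defect] <- unname(p$moduli["implant"])

  distal <- which(g$nodes$y <= 1e-12)
  top <- which(g$nodes$y >= p$height - 1e-12)
  band <- p$width * p$load_frac / 2
  joint <- top[abs(g$nodes$x[top] - p$width / 2) <= band + 1e-12]

  mesh <- bone_mesh(
    nodes = g$nodes,
    elements = elems,
    node_sets = list(distal_fix = distal, joint_load = joint),
    element_sets = list(
      cortical = cortical,
      cancellous = cancellous,
      defect = defect
    ),
    fixed_set = "distal_fix"
  )
  mesh$initial_modulus <- initial_modulus
  mesh$pre_defect_modulus <- pre_defect_modulus
  mesh
}
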