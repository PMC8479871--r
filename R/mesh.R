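#' Triangulated cell-membrane surface
#'
#' A `cell_mesh` is a closed, orientable triangulated surface representing the
#' plasma membrane of a single (approximately truncated-sphere shaped) cell.
#' Nodes carry spherical surface coordinates: the polar angle `theta` in
#' `[-pi/2, pi/2]` (with `-pi/2` at the centre of the ventral, substrate-facing
#' membrane) and the periodic azimuth `phi` in `[-pi, pi]`. Nodes on the
#' ventral (adherent) membrane are flagged, and the polar angle of the contact
#' perimeter -- the ring separating adherent from free membrane -- is stored as
#' `theta_adh`.
#'
#' @param nodes numeric matrix (n x 3) of node positions in micrometres.
#' @param triangles integer matrix (m x 3) of node indices, outward oriented.
#' @param center numeric length-3 cell centre.
#' @param theta,phi per-node surface coordinates (radians); computed from the
#'   geometry when omitted.
#' @param adherent logical per-node flag for ventral-membrane nodes.
#' @param theta_adh polar angle of the contact perimeter (radians), `NA` for a
#'   cell with no adhered patch.
#' @param R_eff effective spherical radius (micrometres); median free-node
#'   distance from the centre when omitted.
#' @param validate check closedness and orientability (default `TRUE`).
#'
#' @return An object of class `cell_mesh`: a list with elements `nodes`,
#'   `triangles`, `center`, `theta`, `phi`, `adherent`, `theta_adh`,
#'   `node_area`, `R_eff`.
#' @export
cell_mesh <- function(nodes, triangles, center = colMeans(nodes),
                      theta = NULL, phi = NULL,
                      adherent = rep(FALSE, nrow(nodes)),
                      theta_adh = NA_real_, R_eff = NULL,
                      validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(nodes) == 3, ncol(triangles) == 3)
  if (validate) {
    check_closed_surface(nodes, triangles)
    triangles <- orient_outward(nodes, triangles, center)
  }
  rel <- sweep(nodes, 2, center)
  r <- sqrt(rowSums(rel^2))
  if (is.null(theta)) theta <- asin(pmin(1, pmax(-1, rel[, 3] / r)))
  if (is.null(phi)) phi <- atan2(rel[, 2], rel[, 1])
  if (is.null(R_eff)) {
    free <- if (any(!adherent)) !adherent else rep(TRUE, nrow(nodes))
    R_eff <- stats::median(r[free])
  }
  m <- structure(list(
    nodes = nodes, triangles = triangles, center = as.numeric(center),
    theta = as.numeric(theta), phi = as.numeric(phi),
    adherent = as.logical(adherent), theta_adh = theta_adh,
    node_area = NULL, R_eff = R_eff
  ), class = "cell_mesh")
  m$node_area <- node_areas(m)
  m
}

#' @export
print.cell_mesh <- function(x, ...) {
  cat(sprintf(
    "cell_mesh: %d nodes, %d triangles\n  A_mem = %.2f um^2, mean node area = %.3f um^2, R_eff = %.2f um\n",
    nrow(x$nodes), nrow(x$triangles), mesh_area(x),
    mesh_area(x) / nrow(x$nodes), x$R_eff))
  if (any(x$adherent)) {
    cat(sprintf("  adherent nodes: %d, theta_adh = %.3f rad, A_adh = %.2f um^2\n",
                sum(x$adherent), x$theta_adh, adherent_area(x)))
  } else {
    cat("  no adherent patch (full sphere)\n")
  }
  invisible(x)
}

#' Per-triangle areas
#' @param mesh a `cell_mesh`.
#' @return numeric vector of triangle areas (um^2).
#' @export
triangle_areas <- function(mesh) {
  v1 <- mesh$nodes[mesh$triangles[, 1], , drop = FALSE]
  v2 <- mesh$nodes[mesh$triangles[, 2], , drop = FALSE]
  v3 <- mesh$nodes[mesh$triangles[, 3], , drop = FALSE]
  cr <- vec_cross(v2 - v1, v3 - v1)
  0.5 * sqrt(rowSums(cr^2))
}

#' Per-node areas (one third of each incident triangle)
#' @inheritParams triangle_areas
#' @return numeric vector of node areas (um^2); sums to the total mesh area.
#' @export
node_areas <- function(mesh) {
  ta <- triangle_areas(mesh)
  a <- numeric(nrow(mesh$nodes))
  for (k in 1:3) {
    s <- tapply(ta, mesh$triangles[, k], sum)
    a[as.integer(names(s))] <- a[as.integer(names(s))] + s
  }
  a / 3
}

#' Total membrane area
#' @inheritParams triangle_areas
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

#' Adhered (ventral) membrane area from triangles whose vertices are all
#' adherent
#' @inheritParams triangle_areas
#' @export
adherent_area <- function(mesh) {
  if (!any(mesh$adherent)) return(0)
  adh <- matrix(mesh$adherent[mesh$triangles], ncol = 3)
  sum(triangle_areas(mesh)[rowSums(adh) == 3])
}

#' Enclosed cell volume by tetrahedral decomposition about the centre
#' @inheritParams triangle_areas
#' @return volume in cubic micrometres.
#' @export
mesh_volume <- function(mesh) {
  v1 <- sweep(mesh$nodes[mesh$triangles[, 1], , drop = FALSE], 2, mesh$center)
  v2 <- sweep(mesh$nodes[mesh$triangles[, 2], , drop = FALSE], 2, mesh$center)
  v3 <- sweep(mesh$nodes[mesh$triangles[, 3], , drop = FALSE], 2, mesh$center)
  sum(rowSums(vec_cross(v1, v2) * v3)) / 6
}

#' Unique undirected edges of a mesh
#' @inheritParams triangle_areas
#' @return integer matrix (e x 2), each row an edge with node1 < node2.
#' @export
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Mean edge length of a mesh
#' @inheritParams triangle_areas
#' @export
mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)
  mean(sqrt(rowSums((mesh$nodes[e[, 1], ] - mesh$nodes[e[, 2], ])^2)))
}

#' Euler characteristic V - E + F
#' @inheritParams triangle_areas
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$nodes) - nrow(mesh_edges(mesh)) + nrow(mesh$triangles)
}

#' One-ring vertex neighbourhoods
#' @inheritParams triangle_areas
#' @return list of integer vectors, neighbours of each node.
#' @export
vertex_neighbors <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$nodes)
  nb <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = 1:n))
  lapply(nb, function(v) sort(unique(v)))
}

# ---- internal geometry helpers ---------------------------------------------

vec_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

normalize_rows <- function(m) m / sqrt(rowSums(m^2))

# Every edge of a closed orientable triangulated surface is shared by exactly
# two triangles, with opposite orientation.
check_closed_surface <- function(nodes, triangles, call. = FALSE) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2)) {
    stop("mesh is not a closed surface: ", sum(cnt != 2),
         " edge(s) not shared by exactly two triangles", call. = call.)
  }
  invisible(TRUE)
}

orient_outward <- function(nodes, triangles, center) {
  v1 <- sweep(nodes[triangles[, 1], , drop = FALSE], 2, center)
  v2 <- sweep(nodes[triangles[, 2], , drop = FALSE], 2, center)
  v3 <- sweep(nodes[triangles[, 3], , drop = FALSE], 2, center)
  nrm <- vec_cross(v2 - v1, v3 - v1)
  flip <- rowSums(nrm * (v1 + v2 + v3)) < 0
  triangles[flip, ] <- triangles[flip, c(1, 3, 2)]
  triangles
}

#' Delaunay triangulation of unit directions on the sphere
#'
#' Triangulates a set of quasi-uniform unit vectors into a closed surface
#' triangulation. One direction is chosen as projection pole; the remaining
#' directions are stereographically projected onto the plane, where their
#' planar Delaunay triangulation is computed (stereographic projection maps
#' circles to circles, so the planar Delaunay triangles are Delaunay on the
#' sphere). The cap around the pole is closed by fanning the convex-hull
#' boundary polygon to the pole direction. Validity (closed, Euler
#' characteristic 2) is asserted; a handful of alternative poles is tried
#' before giving up.
#'
#' @param dirs numeric matrix (n x 3) of directions; normalised internally.
#' @return integer triangle matrix (m x 3), outward oriented with respect to
#'   the origin of direction space.
#' @export
triangulate_directions <- function(dirs) {
  dirs <- normalize_rows(as.matrix(dirs))
  n <- nrow(dirs)
  if (n < 4) stop("need at least 4 directions")
  cand <- unique(c(which.max(dirs[, 3]), which.min(dirs[, 3]),
                   which.max(dirs[, 1]), which.max(dirs[, 2]), 1L))
  last_err <- NULL
  for (pole in cand) {
    tri <- tryCatch(triangulate_with_pole(dirs, pole),
                    error = function(e) e)
    if (!inherits(tri, "error")) return(tri)
    last_err <- tri
  }
  stop("direction triangulation failed: ", conditionMessage(last_err))
}

triangulate_with_pole <- function(dirs, pole) {
  n <- nrow(dirs)
  p <- dirs[pole, ]
  # rotate pole onto +z
  Rm <- rotation_to_z(p)
  d <- dirs %*% t(Rm)
  keep <- setdiff(seq_len(n), pole)
  z <- d[keep, 3]
  if (any(z > 1 - 1e-12)) stop("duplicate direction at projection pole")
  u <- d[keep, 1] / (1 - z)
  v <- d[keep, 2] / (1 - z)
  tm <- interp::tri.mesh(u, v)
  tri_loc <- interp::triangles(tm)[, 1:3, drop = FALSE]
  hull <- interp::convex.hull(tm)
  hi <- hull$i
  tri <- matrix(keep[tri_loc], ncol = 3)
  fan <- cbind(pole, keep[hi], keep[c(hi[-1], hi[1])])
  tri <- rbind(tri, fan)
  check_closed_surface(dirs, tri)
  ec <- nrow(dirs) - nrow(unique_edges(tri)) + nrow(tri)
  if (ec != 2) stop("triangulation has Euler characteristic ", ec)
  orient_outward(dirs, tri, c(0, 0, 0))
}

unique_edges <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

rotation_to_z <- function(p) {
  p <- p / sqrt(sum(p^2))
  z <- c(0, 0, 1)
  c_ <- sum(p * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  axis <- c(p[2] * z[3] - p[3] * z[2], p[3] * z[1] - p[1] * z[3],
            p[1] * z[2] - p[2] * z[1])
  s <- sqrt(sum(axis^2))
  axis <- axis / s
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

#' Quasi-uniform directions on the unit sphere (Fibonacci lattice)
#' @param n number of directions.
#' @return numeric matrix (n x 3) of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  th <- ga * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}
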