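#' Locate the membrane surface in a 4D stack
#'
#' The membrane is the locus of maximal temporal intensity fluctuation: for
#' every voxel the standard deviation over time is computed, and for each of
#' `n_directions` quasi-uniform ray directions from the cell centre (intensity
#' centroid of the time-averaged stack) the radial profile of this fluctuation
#' volume is sampled by trilinear interpolation. The membrane radius along a
#' ray is the profile argmax, refined to sub-voxel precision by a local
#' quadratic fit; ties are broken toward the larger radius so the outer shell,
#' not the cytosol, is selected. Rays whose argmax falls at a profile end (no
#' interior maximum) are flagged and filled from the nearest non-flagged
#' directions; reconstruction fails if more than 20% of rays are flagged.
#'
#' @param stack a `voxel_stack` (needs at least 3 time points).
#' @param meta a [stack_metadata()]; defaults to the stack's own metadata.
#' @param n_directions number of rays (default 500).
#' @return A numeric matrix (n_directions x 3) of surface points
#'   (micrometres), with the cell centre as attribute `"center"`.
#' @export
locate_membrane <- function(stack, meta = stack$meta, n_directions = 500) {
  d <- dim(stack$data)
  if (d[4] < 3) stop("need at least 3 time points")
  sp <- c(meta$dx, meta$dy, meta$dz)
  mean_t <- apply(stack$data, 1:3, mean)
  var_t <- apply(stack$data^2, 1:3, mean) - mean_t^2
  var_t[var_t < 0] <- 0
  sd_t <- sqrt(var_t)
  if (max(sd_t) <= 1e-12 * max(mean_t, 1e-300)) {
    stop("reconstruction failure: stack shows no temporal variation")
  }
  tot <- sum(mean_t)
  if (tot <= 0) stop("empty stack")
  gx <- stack$origin[1] + (seq_len(d[1]) - 1) * sp[1]
  gy <- stack$origin[2] + (seq_len(d[2]) - 1) * sp[2]
  gz <- stack$origin[3] + (seq_len(d[3]) - 1) * sp[3]
  cx <- c(sum(apply(mean_t, 1, sum) * gx),
          sum(apply(mean_t, 2, sum) * gy),
          sum(apply(mean_t, 3, sum) * gz)) / tot
  dirs <- fibonacci_sphere(n_directions)
  lob <- c(min(gx), min(gy), min(gz))
  hib <- c(max(gx), max(gy), max(gz))
  dr <- min(sp) / 2
  radii <- numeric(n_directions)
  flagged <- logical(n_directions)
  for (i in seq_len(n_directions)) {
    # ray length to the box boundary along this direction
    v <- dirs[i, ]
    tmax <- Inf
    for (ax in 1:3) {
      if (abs(v[ax]) > 1e-12) {
        tb <- ((if (v[ax] > 0) hib[ax] else lob[ax]) - cx[ax]) / v[ax]
        tmax <- min(tmax, tb)
      }
    }
    if (tmax - dr < 2 * dr) {
      flagged[i] <- TRUE
      next
    }
    rr <- seq(dr, tmax - dr, by = dr)
    pts <- cbind(cx[1] + rr * v[1], cx[2] + rr * v[2], cx[3] + rr * v[3])
    prof <- trilinear(sd_t, pts, stack$origin, sp)
    jm <- length(prof) + 1 - which.max(rev(prof))  # ties -> larger radius
    if (jm <= 1 || jm >= length(prof) || prof[jm] <= 1e-12) {
      flagged[i] <- TRUE
      next
    }
    # a blurred peak falling between voxel planes interpolates to a flat
    # top; centre on the plateau before refining
    plateau <- which(prof >= prof[jm] * (1 - 1e-9))
    plateau <- plateau[plateau >= jm - 8 & plateau <= jm + 8]
    jm <- round(mean(range(plateau)))
    # sub-voxel refinement: local quadratic fit over a window matched to the
    # coarsest voxel scale (the finely sampled profile has flat tops where
    # the peak falls between voxel planes, so a 3-point fit is degenerate)
    hw <- max(2 * dr, max(sp))
    wsel <- which(abs(rr - rr[jm]) <= hw)
    if (length(wsel) >= 3) {
      xw <- rr[wsel] - rr[jm]
      cf <- stats::lm.fit(cbind(1, xw, xw^2), prof[wsel])$coefficients
      off <- if (is.finite(cf[3]) && cf[3] < 0) -cf[2] / (2 * cf[3]) else 0
      radii[i] <- rr[jm] + max(-hw, min(hw, off))
    } else {
      radii[i] <- rr[jm]
    }
  }
  if (mean(flagged) > 0.2) {
    stop("reconstruction failure: ", sum(flagged), " of ", n_directions,
         " rays have no interior membrane maximum")
  }
  if (any(flagged)) {
    ok <- which(!flagged)
    for (i in which(flagged)) {
      dp <- dirs[ok, , drop = FALSE] %*% dirs[i, ]
      near <- ok[order(dp, decreasing = TRUE)[1:min(3, length(ok))]]
      radii[i] <- mean(radii[near])
    }
  }
  pts <- sweep(dirs * radii, 2, cx, "+")
  attr(pts, "center") <- cx
  pts
}

trilinear <- function(vol, pts, origin, sp) {
  d <- dim(vol)
  vc <- sweep(sweep(pts, 2, origin), 2, sp, "/") + 1
  vc[, 1] <- pmin(pmax(vc[, 1], 1), d[1] - 1e-9)
  vc[, 2] <- pmin(pmax(vc[, 2], 1), d[2] - 1e-9)
  vc[, 3] <- pmin(pmax(vc[, 3], 1), d[3] - 1e-9)
  fl <- pmin(floor(vc), rep(d - 1, each = nrow(vc)))
  fr <- vc - fl
  out <- numeric(nrow(pts))
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    w <- (if (ox == 0) 1 - fr[, 1] else fr[, 1]) *
         (if (oy == 0) 1 - fr[, 2] else fr[, 2]) *
         (if (oz == 0) 1 - fr[, 3] else fr[, 3])
    lin <- (fl[, 3] + oz - 1) * d[1] * d[2] + (fl[, 2] + oy - 1) * d[1] +
      fl[, 1] + ox
    out <- out + w * vol[lin]
  }
  out
}

#' Triangulate a star-shaped membrane point cloud
#'
#' Builds a closed Delaunay mesh over the directions of the point cloud from
#' the cell centre, then resamples it to a quasi-uniform Fibonacci direction
#' set sized so that the mean node area matches `target_node_area`
#' (0.3 um^2 by default), with radii interpolated from the nearest cloud
#' directions (inverse-distance weights). Node positions are finally relaxed
#' by one pass of [smooth_nodes()].
#'
#' @param points numeric matrix (n x 3) of surface points (needs `n >= 100`),
#'   optionally with a `"center"` attribute.
#' @param target_node_area desired mean node area in um^2.
#' @param smooth apply the one-pass neighbour smoothing (default `TRUE`).
#' @return A [cell_mesh()] (no adhesion labels yet; see
#'   [detect_contact_perimeter()]).
#' @export
triangulate_surface <- function(points, target_node_area = 0.3,
                                smooth = TRUE) {
  points <- as.matrix(points)
  if (nrow(points) < 100) stop("need at least 100 points")
  center <- attr(points, "center")
  if (is.null(center)) center <- colMeans(points)
  rel <- sweep(points, 2, center)
  sv <- svd(rel)$d
  if (sv[3] < 1e-3 * sv[1]) {
    stop("triangulation error: point cloud is degenerate (planar)")
  }
  r <- sqrt(rowSums(rel^2))
  dirs <- rel / r
  # pass 1: area estimate from the raw-cloud triangulation
  tri0 <- triangulate_directions(dirs)
  m0 <- cell_mesh(points, tri0, center = center, validate = FALSE)
  A <- mesh_area(m0)
  for (it in 1:2) {
    n_new <- max(100L, round(A / target_node_area))
    nd <- fibonacci_sphere(n_new)
    rad <- interp_radii(nd, dirs, r)
    nodes <- sweep(nd * rad, 2, center, "+")
    tri <- triangulate_directions(nd)
    mesh <- cell_mesh(nodes, tri, center = center)
    A <- mesh_area(mesh)
  }
  if (smooth) mesh <- smooth_nodes(mesh)
  mesh
}

# inverse-distance (in direction space) interpolation of radii from the k
# nearest cloud directions
interp_radii <- function(new_dirs, dirs, r, k = 6L) {
  out <- numeric(nrow(new_dirs))
  step <- 2000L
  for (s in seq(1, nrow(new_dirs), by = step)) {
    e <- min(s + step - 1, nrow(new_dirs))
    dp <- new_dirs[s:e, , drop = FALSE] %*% t(dirs)
    dp[dp > 1] <- 1
    dp[dp < -1] <- -1
    for (j in seq_len(e - s + 1)) {
      ang <- acos(dp[j, ])
      near <- order(ang)[seq_len(k)]
      w <- 1 / pmax(ang[near], 1e-9)
      out[s + j - 1] <- sum(w * r[near]) / sum(w)
    }
  }
  out
}

#' One-pass neighbour-weighted node smoothing
#'
#' Replaces every node position by a Gaussian-weighted average of itself and
#' its one-ring neighbours, with weights from inter-node distance and width
#' `kernel_sd` (default: the mean edge length). Topology is unchanged; a
#' `kernel_sd` approaching zero reduces to the identity. Repeated application
#' behaves like Laplacian smoothing and progressively shrinks the surface;
#' the pipeline applies a single pass.
#'
#' @param mesh a [cell_mesh()].
#' @param kernel_sd kernel width in micrometres.
#' @return The smoothed [cell_mesh()].
#' @export
smooth_nodes <- function(mesh, kernel_sd = 0.5 * mean_edge_length(mesh)) {
  nb <- vertex_neighbors(mesh)
  n <- nrow(mesh$nodes)
  newpos <- mesh$nodes
  if (kernel_sd > 0) {
    for (i in seq_len(n)) {
      j <- nb[[i]]
      dvec <- mesh$nodes[j, , drop = FALSE] -
        matrix(mesh$nodes[i, ], length(j), 3, byrow = TRUE)
      w <- exp(-rowSums(dvec^2) / (2 * kernel_sd^2))
      wsum <- 1 + sum(w)
      newpos[i, ] <- (mesh$nodes[i, ] + colSums(w * mesh$nodes[j, , drop = FALSE])) / wsum
    }
  }
  cell_mesh(newpos, mesh$triangles, center = mesh$center,
            adherent = mesh$adherent, theta_adh = mesh$theta_adh,
            validate = FALSE)
}

#' Sample per-node signal time series from a stack
#'
#' For every node and time point the intensity is the mean of trilinear
#' samples taken at the node position and one voxel inward/outward along the
#' node's ray from the cell centre (a radial window of +/- 1 voxel).
#'
#' @param stack a `voxel_stack`.
#' @param mesh a [cell_mesh()] inside the stack bounds.
#' @param meta a [stack_metadata()]; defaults to the stack's own metadata.
#' @return A [signal_field()].
#' @export
sample_signal <- function(stack, mesh, meta = stack$meta) {
  d <- dim(stack$data)
  sp <- c(meta$dx, meta$dy, meta$dz)
  dirs <- normalize_rows(sweep(mesh$nodes, 2, mesh$center))
  step <- min(sp)
  pts <- rbind(mesh$nodes - step * dirs, mesh$nodes, mesh$nodes + step * dirs)
  vc <- sweep(sweep(pts, 2, stack$origin), 2, sp, "/") + 1
  if (any(vc < 1) || any(vc > rep(d[1:3], each = nrow(pts)))) {
    stop("sampling error: node outside stack")
  }
  n <- nrow(mesh$nodes)
  nt <- d[4]
  vals <- matrix(0, n, nt)
  for (j in seq_len(nt)) {
    s <- trilinear(stack$data[, , , j], pts, stack$origin, sp)
    vals[, j] <- (s[1:n] + s[n + 1:n] + s[2 * n + 1:n]) / 3
  }
  signal_field(vals, dt = meta$dt, t0 = 0)
}

#' Detect the adhered membrane and the contact perimeter
#'
#' Cells sit on a flat substrate, so the supporting plane is the minimum-z
#' plane of the mesh. Nodes within `flatness_tol` of it are flagged adherent;
#' the contact perimeter angle `theta_adh` is the area-weighted mean polar
#' angle over the boundary ring (adherent nodes with at least one free
#' neighbour). Ventral nodes are then re-parameterised in `theta` linearly in
#' radial position from `-pi/2` (disc centre) to `theta_adh` (rim).
#'
#' @param mesh a [cell_mesh()].
#' @param flatness_tol distance tolerance to the supporting plane
#'   (micrometres, default 0.5, the typical axial voxel size).
#' @return The mesh with updated `adherent`, `theta_adh` and ventral `theta`.
#'   With no node near the plane the mesh is returned unchanged with
#'   `theta_adh = NA` (a full sphere, contact angle 0).
#' @export
detect_contact_perimeter <- function(mesh, flatness_tol = 0.5) {
  z <- mesh$nodes[, 3]
  zmin <- min(z)
  cand <- z < zmin + flatness_tol
  if (all(cand)) {
    stop("all nodes within flatness_tol of the supporting plane; ",
         "mesh is not a closed cell surface")
  }
  no_patch <- function(mesh) {
    mesh$adherent <- rep(FALSE, nrow(mesh$nodes))
    mesh$theta_adh <- NA_real_
    mesh$R_eff <- fit_sphere(mesh$nodes)$radius
    mesh
  }
  # a handful of touching nodes is not an adhered patch
  if (sum(cand) < 6) return(no_patch(mesh))
  # centre the tolerance band on the ventral plane rather than hanging it
  # from the single lowest node
  core <- z < zmin + flatness_tol / 2
  zplane <- stats::median(z[core])
  adherent <- z < zplane + flatness_tol
  # flat-disc test: an adhered patch covers far more area than the spherical
  # cap of the same height; a bare sphere bottom does not
  h <- max(z[adherent]) - min(z[adherent])
  a_patch <- sum(mesh$node_area[adherent])
  a_cap <- 2 * pi * mesh$R_eff * max(h, 1e-6)
  if (a_patch < 1.4 * a_cap) return(no_patch(mesh))
  nb <- vertex_neighbors(mesh)
  ring <- which(adherent & vapply(seq_along(nb), function(i) {
    any(!adherent[nb[[i]]])
  }, logical(1)))
  w <- mesh$node_area[ring]
  theta_adh <- sum(w * mesh$theta[ring]) / sum(w)
  cx <- mesh$center
  rxy <- sqrt((mesh$nodes[, 1] - cx[1])^2 + (mesh$nodes[, 2] - cx[2])^2)
  r_rim <- stats::median(rxy[ring])
  th <- mesh$theta
  th[adherent] <- -pi / 2 +
    pmin(1, rxy[adherent] / r_rim) * (theta_adh + pi / 2)
  mesh$adherent <- adherent
  mesh$theta_adh <- theta_adh
  mesh$theta <- th
  # effective spherical radius: least-squares sphere through the free nodes
  # clear of the rounded rim (the intensity centroid used for ray casting is
  # not the sphere centre of a truncated cell)
  clear <- !adherent & th > theta_adh + 0.2
  if (sum(clear) < 10) clear <- !adherent
  fit <- fit_sphere(mesh$nodes[clear, , drop = FALSE])
  mesh$R_eff <- fit$radius
  mesh
}

# algebraic least-squares sphere fit: |x - c|^2 = R^2
fit_sphere <- function(X) {
  A <- cbind(2 * X, 1)
  b <- rowSums(X^2)
  p <- stats::lm.fit(A, b)$coefficients
  center <- p[1:3]
  list(center = unname(center),
       radius = sqrt(max(p[4] + sum(center^2), 0)))
}

#' Full stack-to-cell reconstruction
#'
#' Convenience wrapper chaining [locate_membrane()], [triangulate_surface()],
#' [detect_contact_perimeter()] and [sample_signal()].
#'
#' @param stack a `voxel_stack`.
#' @param meta a [stack_metadata()]; defaults to the stack's own metadata.
#' @param n_directions rays for membrane localisation.
#' @param target_node_area mean node area of the final mesh (um^2).
#' @param flatness_tol adhesion tolerance (um); see
#'   [detect_contact_perimeter()].
#' @return list with `mesh` and `signal`.
#' @export
reconstruct_cell <- function(stack, meta = stack$meta, n_directions = 500,
                             target_node_area = 0.3, flatness_tol = 0.5) {
  pts <- locate_membrane(stack, meta, n_directions)
  mesh <- triangulate_surface(pts, target_node_area)
  mesh <- detect_contact_perimeter(mesh, flatness_tol)
  sig <- sample_signal(stack, mesh, meta)
  list(mesh = mesh, signal = sig)
}
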