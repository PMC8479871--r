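#' Adhesion area ratio of a truncated sphere at contact angle Omega
#'
#' The dimensionless ratio between ventral (adhered) and entire membrane
#' area, `r_a = sin^2(Omega) / (4 - (1 - cos(Omega)))`, with the sphere
#' radius cancelling. It rises monotonically from 0 at `Omega = 0` to 1/3 at
#' `Omega = pi/2`. This model form treats the denominator as the full sphere
#' area minus the spherical cap cut away by the substrate; the exact
#' truncated-sphere ratio (free cap plus closing disc) agrees with it at both
#' endpoints and deviates by a few percent in between -- see
#' [area_ratio_exact()].
#'
#' @param omega contact angle(s) in radians, in `[0, pi/2]`.
#' @return r_a, vectorised.
#' @export
area_ratio <- function(omega) {
  if (any(omega < -1e-12 | omega > pi / 2 + 1e-12)) {
    stop("omega must lie in [0, pi/2]")
  }
  sin(omega)^2 / (4 - (1 - cos(omega)))
}

#' Exact truncated-sphere adhesion area ratio
#'
#' Disc area over free-cap-plus-disc area:
#' `pi R^2 sin^2(Omega) / (2 pi R^2 (1 + cos(Omega)) + pi R^2 sin^2(Omega))`.
#' Provided for comparison with the model form [area_ratio()].
#'
#' @inheritParams area_ratio
#' @export
area_ratio_exact <- function(omega) {
  s2 <- sin(omega)^2
  s2 / (2 * (1 + cos(omega)) + s2)
}

#' Contact angle from the adhesion area ratio
#'
#' Numerically inverts [area_ratio()] by bisection on `[0, pi/2]` to
#' `tol`. The closed-form inverse (root of the quadratic
#' `cos^2(Omega) + r_a cos(Omega) + 3 r_a - 1 = 0`) is available as
#' [contact_angle_closed_form()] and agrees with the bisection to the same
#' tolerance; the iterative route is canonical.
#'
#' @param r_a area ratio(s) in `[0, 1/3]` (the range of the model on
#'   `[0, pi/2]`).
#' @param tol bisection tolerance (default 1e-10).
#' @return Omega in radians, vectorised.
#' @export
contact_angle <- function(r_a, tol = 1e-10) {
  if (any(r_a < -1e-12 | r_a > 1 / 3 + 1e-12)) {
    stop("r_a must lie in [0, 1/3]")
  }
  vapply(pmin(pmax(r_a, 0), 1 / 3), function(r) {
    lo <- 0; hi <- pi / 2
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (area_ratio(mid) < r) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Closed-form contact angle from the area ratio
#'
#' Solves the model relation analytically: substituting `c = cos(Omega)`
#' into `r_a = (1 - c^2)/(3 + c)` gives `c^2 + r_a c + 3 r_a - 1 = 0`, hence
#' `Omega = acos((-r_a + sqrt(r_a^2 - 12 r_a + 4)) / 2)`.
#'
#' @inheritParams contact_angle
#' @export
contact_angle_closed_form <- function(r_a) {
  if (any(r_a < -1e-12 | r_a > 1 / 3 + 1e-12)) {
    stop("r_a must lie in [0, 1/3]")
  }
  disc <- pmax(0, r_a^2 - 12 * r_a + 4)
  acos(pmin(1, pmax(-1, (-r_a + sqrt(disc)) / 2)))
}

#' Discrete mean curvature at mesh nodes
#'
#' Cotangent-Laplacian estimate: the mean-curvature normal at node i is
#' `K_i = sum_j (cot a_ij + cot b_ij)(x_i - x_j) / (4 A_i)` over the one-ring,
#' with `A_i` the node area; the mean curvature is `|K_i| / 2` (equal to `1/R`
#' on a sphere of radius R).
#'
#' @param mesh a [cell_mesh()].
#' @return numeric per-node mean curvature (1/um).
#' @export
mesh_curvature <- function(mesh) {
  tr <- mesh$triangles
  n <- nrow(mesh$nodes)
  K <- matrix(0, n, 3)
  for (corner in 1:3) {
    i <- tr[, corner]
    j <- tr[, corner %% 3 + 1]
    k <- tr[, (corner + 1) %% 3 + 1]
    # angle at k, opposite edge (i, j)
    u <- mesh$nodes[i, , drop = FALSE] - mesh$nodes[k, , drop = FALSE]
    v <- mesh$nodes[j, , drop = FALSE] - mesh$nodes[k, , drop = FALSE]
    cot <- rowSums(u * v) / pmax(sqrt(rowSums(vec_cross(u, v)^2)), 1e-12)
    e <- mesh$nodes[i, , drop = FALSE] - mesh$nodes[j, , drop = FALSE]
    for (c3 in 1:3) {
      K[, c3] <- K[, c3] + unname(tapply_add(cot * e[, c3], i, n)) -
        unname(tapply_add(cot * e[, c3], j, n))
    }
  }
  sqrt(rowSums(K^2)) / (4 * mesh$node_area)
}

tapply_add <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Cell-shape descriptors
#'
#' Computes from a closed mesh with adhesion labels: total membrane area
#' `A_mem` (um^2), ventral area `A_adh`, enclosed volume `V` (pL), adhesion
#' area ratio `r_a = A_adh/A_mem`, contact angle `Omega` from the inverse of
#' [area_ratio()], effective radius `R` and the maximal discrete mean
#' curvature `kappa_max` (1/um) over the contact-perimeter ring (`NA` for a
#' cell without an adhered patch).
#'
#' @param mesh a [cell_mesh()].
#' @return A `cell_geometry`: list with `V_pL`, `A_adh`, `A_mem`, `r_a`,
#'   `omega`, `R`, `kappa_max`.
#' @export
shape_descriptors <- function(mesh) {
  check_closed_surface(mesh$nodes, mesh$triangles)
  A_mem <- mesh_area(mesh)
  A_adh <- adherent_area(mesh)
  V <- mesh_volume(mesh)
  r_a <- A_adh / A_mem
  omega <- if (r_a <= 0) 0 else contact_angle(min(r_a, 1 / 3))
  kmax <- NA_real_
  ring <- perimeter_ring(mesh)
  if (length(ring)) kmax <- max(mesh_curvature(mesh)[ring])
  structure(list(V_pL = V * 1e-3, A_adh = A_adh, A_mem = A_mem, r_a = r_a,
                 omega = omega, R = mesh$R_eff, kappa_max = kmax),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "cell_geometry: V = %.3f pL, A_mem = %.1f um^2, A_adh = %.1f um^2\n  r_a = %.3f, Omega = %.1f deg, R = %.2f um, kappa_max = %s 1/um\n",
    x$V_pL, x$A_mem, x$A_adh, x$r_a, x$omega * 180 / pi, x$R,
    if (is.na(x$kappa_max)) "NA" else sprintf("%.2f", x$kappa_max)))
  invisible(x)
}
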