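#' Auxiliary angle of the Mollweide projection
#'
#' Solves `2*gamma + sin(2*gamma) = pi * sin(latitude)` by Newton-Raphson
#' iteration from `gamma0 = latitude`. The poles are returned analytically
#' (`gamma = +/- pi/2`), where the Newton derivative vanishes.
#'
#' @param latitude latitude(s) in radians, `|latitude| <= pi/2`.
#' @param tol convergence tolerance (default 1e-10).
#' @return gamma in radians, vectorised over `latitude`.
#' @export
solve_gamma <- function(latitude, tol = 1e-10) {
  if (any(abs(latitude) > pi / 2 + 1e-12)) stop("|latitude| must be <= pi/2")
  g <- latitude
  pole <- abs(latitude) > pi / 2 - 1e-9
  g[pole] <- sign(latitude[pole]) * pi / 2
  act <- which(!pole)
  if (length(act)) {
    target <- pi * sin(latitude[act])
    gi <- latitude[act]
    for (it in 1:100) {
      f <- 2 * gi + sin(2 * gi) - target
      step <- f / (2 + 2 * cos(2 * gi))
      gi <- gi - step
      if (all(abs(step) < tol)) break  # converge on gamma, not the residual
    }
    if (it == 100 && any(abs(step) >= tol)) {
      stop("Newton-Raphson failed to converge")
    }
    g[act] <- gi
  }
  g
}

#' Mollweide equal-area projection
#'
#' Maps longitude (azimuth, horizontal map axis) and latitude (polar angle,
#' vertical map axis) onto the 2:1 Mollweide ellipse:
#' `x = (2*sqrt(2)/pi) * longitude * cos(gamma)`, `y = sqrt(2) * sin(gamma)`,
#' with the auxiliary angle from [solve_gamma()]. The projection preserves
#' area: equal membrane patches occupy equal map area.
#'
#' @param longitude azimuth in radians, in `[-pi, pi]`.
#' @param latitude polar angle in radians, in `[-pi/2, pi/2]`.
#' @param tol tolerance passed to [solve_gamma()].
#' @return data.frame with columns `x`, `y`, `gamma`.
#' @export
mollweide_project <- function(longitude, latitude, tol = 1e-10) {
  g <- solve_gamma(latitude, tol)
  data.frame(x = (2 * sqrt(2) / pi) * longitude * cos(g),
             y = sqrt(2) * sin(g),
             gamma = g)
}

#' Inverse Mollweide projection
#' @param x,y map coordinates inside the ellipse.
#' @return data.frame with `longitude`, `latitude` (radians); `NA` outside the
#'   ellipse.
#' @export
mollweide_inverse <- function(x, y) {
  g <- asin(pmin(1, pmax(-1, y / sqrt(2))))
  lat <- asin(pmin(1, pmax(-1, (2 * g + sin(2 * g)) / pi)))
  lon <- pi * x / (2 * sqrt(2) * cos(g))
  bad <- (x / (2 * sqrt(2)))^2 + (y / sqrt(2))^2 > 1 + 1e-12 |
    abs(lon) > pi + 1e-9
  lon[bad] <- NA
  lat[bad] <- NA
  data.frame(longitude = lon, latitude = lat)
}

#' Rasterise a per-node field as a Mollweide map
#'
#' Every map pixel is inverted to `(phi, theta)` surface coordinates and
#' interpolated from the mesh: the containing surface triangle (searched among
#' the triangles incident to the nearest node in coordinate space) is
#' interpolated barycentrically, with nearest-node fallback. Pixels outside
#' the ellipse are `NA`.
#'
#' @param mesh a [cell_mesh()].
#' @param node_values numeric per-node values.
#' @param nx,ny raster size (default 360 x 180).
#' @return A `mollweide_map`: list with `z` (nx x ny matrix), `x`, `y` pixel
#'   centres and `theta_adh`.
#' @export
render_map <- function(mesh, node_values, nx = 360, ny = 180) {
  stopifnot(length(node_values) == nrow(mesh$nodes))
  xs <- seq(-2 * sqrt(2), 2 * sqrt(2), length.out = nx)
  ys <- seq(-sqrt(2), sqrt(2), length.out = ny)
  gg <- expand.grid(x = xs, y = ys)
  ll <- mollweide_inverse(gg$x, gg$y)
  ok <- which(!is.na(ll$longitude))
  z <- rep(NA_real_, nrow(gg))
  if (length(ok)) {
    pd <- cbind(cos(ll$latitude[ok]) * cos(ll$longitude[ok]),
                cos(ll$latitude[ok]) * sin(ll$longitude[ok]),
                sin(ll$latitude[ok]))
    nd <- cbind(cos(mesh$theta) * cos(mesh$phi),
                cos(mesh$theta) * sin(mesh$phi),
                sin(mesh$theta))
    inc <- triangles_by_node(mesh)
    step <- 20000L
    vals <- numeric(length(ok))
    for (s in seq(1, length(ok), by = step)) {
      e <- min(s + step - 1, length(ok))
      dp <- pd[s:e, , drop = FALSE] %*% t(nd)
      nearest <- max.col(dp)
      for (j in seq_len(e - s + 1)) {
        vals[s + j - 1] <- interp_on_sphere(pd[s + j - 1, ], nearest[j], nd,
                                            mesh$triangles, inc, node_values)
      }
    }
    z[ok] <- vals
  }
  structure(list(z = matrix(z, nx, ny), x = xs, y = ys,
                 theta_adh = mesh$theta_adh),
            class = "mollweide_map")
}

triangles_by_node <- function(mesh) {
  n <- nrow(mesh$nodes)
  idx <- rep(seq_len(nrow(mesh$triangles)), 3)
  split(idx, factor(as.vector(mesh$triangles), levels = 1:n))
}

interp_on_sphere <- function(p, nearest, nd, triangles, inc, vals) {
  for (f in inc[[nearest]]) {
    v <- triangles[f, ]
    A <- t(nd[v, , drop = FALSE])
    b <- tryCatch(solve(A, p), error = function(e) NULL)
    if (!is.null(b) && all(b > -1e-9)) {
      b <- pmax(b, 0)
      return(sum(b * vals[v]) / sum(b))
    }
  }
  vals[nearest]
}

#' @export
plot.mollweide_map <- function(x, main = "", col = grDevices::hcl.colors(64),
                               ...) {
  graphics::image(x$x, x$y, x$z, asp = 1, col = col, xlab = "x", ylab = "y",
                  main = main, useRaster = TRUE, ...)
  if (!is.null(x$theta_adh) && !is.na(x$theta_adh)) {
    lon <- seq(-pi, pi, length.out = 181)
    pr <- mollweide_project(lon, rep(x$theta_adh, 181))
    graphics::lines(pr$x, pr$y, lty = 2)
  }
  invisible(x)
}

#' Azimuth-time kymograph of a membrane band
#'
#' Averages the signal over the nodes of a polar band -- `"bottom"` (ventral
#' membrane below the contact perimeter), `"center"` (equatorial band) or
#' `"top"` (upper cap) -- within azimuthal bins, for every time point. Empty
#' azimuth bins are filled by circular linear interpolation.
#'
#' @param signal a [signal_field()].
#' @param mesh the matching [cell_mesh()].
#' @param section `"bottom"`, `"center"` or `"top"`.
#' @param n_phi number of azimuth bins (default 60).
#' @param band_halfwidth half-width of the `"center"`/`"top"` bands in
#'   radians of `theta` (default 0.175, i.e. 0.35 rad bands).
#' @return matrix (n_phi x time) with azimuth-bin centres as attribute
#'   `"phi"` and times as `"time"`.
#' @export
extract_kymograph <- function(signal, mesh, section = c("center", "bottom", "top"),
                              n_phi = 60, band_halfwidth = 0.175) {
  section <- match.arg(section)
  th <- mesh$theta
  sel <- switch(section,
    bottom = {
      if (is.na(mesh$theta_adh)) {
        stop("configuration error: cell has no ventral band (omega = 0)")
      }
      th < mesh$theta_adh
    },
    center = abs(th) <= band_halfwidth,
    top = th > pi / 2 - 2 * band_halfwidth)
  if (!any(sel)) stop("configuration error: empty ", section, " band")
  breaks <- seq(-pi, pi, length.out = n_phi + 1)
  bin <- cut(mesh$phi[sel], breaks, labels = FALSE, include.lowest = TRUE)
  vals <- signal$values[sel, , drop = FALSE]
  out <- matrix(NA_real_, n_phi, ncol(vals))
  for (b in unique(bin)) {
    out[b, ] <- colMeans(vals[bin == b, , drop = FALSE])
  }
  # circular interpolation over empty bins
  if (anyNA(out[, 1])) {
    miss <- which(is.na(out[, 1]))
    have <- which(!is.na(out[, 1]))
    for (b in miss) {
      dist <- pmin(abs(have - b), n_phi - abs(have - b))
      w <- 1 / pmax(dist, 0.5)
      out[b, ] <- colSums(out[have, , drop = FALSE] * w) / sum(w)
    }
  }
  attr(out, "phi") <- (breaks[-1] + breaks[-length(breaks)]) / 2
  attr(out, "time") <- signal_times(signal)
  out
}
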