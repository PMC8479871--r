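#' Real spherical-harmonic basis up to a given degree
#'
#' Evaluates the real spherical harmonics Y_lm, l = 0..l_max, at unit
#' directions (16 functions for the default octupole order l_max = 3),
#' orthonormal on the sphere.
#'
#' @param dirs numeric matrix (n x 3) of unit directions.
#' @param l_max maximum degree (default 3).
#' @return numeric matrix (n x (l_max+1)^2).
#' @export
sh_basis <- function(dirs, l_max = 3) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  cols <- list(rep(1 / sqrt(4 * pi), length(z)))
  if (l_max >= 1) {
    c1 <- sqrt(3 / (4 * pi))
    cols <- c(cols, list(c1 * y, c1 * z, c1 * x))
  }
  if (l_max >= 2) {
    cols <- c(cols, list(
      0.5 * sqrt(15 / pi) * x * y,
      0.5 * sqrt(15 / pi) * y * z,
      0.25 * sqrt(5 / pi) * (3 * z^2 - 1),
      0.5 * sqrt(15 / pi) * x * z,
      0.25 * sqrt(15 / pi) * (x^2 - y^2)))
  }
  if (l_max >= 3) {
    cols <- c(cols, list(
      0.25 * sqrt(35 / (2 * pi)) * y * (3 * x^2 - y^2),
      0.5 * sqrt(105 / pi) * x * y * z,
      0.25 * sqrt(21 / (2 * pi)) * y * (5 * z^2 - 1),
      0.25 * sqrt(7 / pi) * z * (5 * z^2 - 3),
      0.25 * sqrt(21 / (2 * pi)) * x * (5 * z^2 - 1),
      0.25 * sqrt(105 / pi) * z * (x^2 - y^2),
      0.25 * sqrt(35 / (2 * pi)) * x * (x^2 - 3 * y^2)))
  }
  if (l_max > 3) stop("l_max > 3 not implemented")
  do.call(cbind, cols)
}

#' Track the activity-domain peak over time
#'
#' Per time point the node signal is projected onto real spherical harmonics
#' up to degree `l_max` (least squares on the scattered node directions) and
#' reconstructed; the smoothed global maximum defines the domain peak. The
#' peak position is refined below node resolution by an intensity-weighted
#' centroid of the nodes within the upper part of the reconstructed profile,
#' reprojected onto the surface. Frames whose reconstructed contrast
#' (max minus mean) is below `contrast_floor` times the best frame's contrast
#' are skipped; if no frame has appreciable absolute contrast the track is
#' empty.
#'
#' @param signal a [signal_field()].
#' @param mesh the matching [cell_mesh()].
#' @param l_max spherical-harmonic order (default 3, the octupole moment).
#' @param contrast_floor relative contrast floor (default 0.2).
#' @return A `domain_track`: data.frame with `frame`, `time`, `x`, `y`, `z`,
#'   `contrast`.
#' @export
track_domain <- function(signal, mesh, l_max = 3, contrast_floor = 0.2) {
  dirs <- normalize_rows(sweep(mesh$nodes, 2, mesh$center))
  Y <- sh_basis(dirs, l_max)
  qr_Y <- qr(Y)
  coef <- qr.coef(qr_Y, signal$values)
  recon <- Y %*% coef
  contrast <- apply(recon, 2, max) - colMeans(recon)
  best <- max(contrast)
  scale_ref <- stats::sd(signal$values)
  if (best <= 1e-10 || best < 1e-3 * scale_ref) {
    return(structure(data.frame(frame = integer(0), time = numeric(0),
                                x = numeric(0), y = numeric(0),
                                z = numeric(0), contrast = numeric(0)),
                     class = c("domain_track", "data.frame")))
  }
  keep <- which(contrast >= contrast_floor * best)
  tt <- signal_times(signal)
  r_node <- sqrt(rowSums(sweep(mesh$nodes, 2, mesh$center)^2))
  pos <- matrix(0, length(keep), 3)
  for (ii in seq_along(keep)) {
    f <- recon[, keep[ii]]
    thr <- max(f) - 0.33 * (max(f) - mean(f))
    sel <- which(f >= thr)
    w <- f[sel] - thr
    if (sum(w) <= 0) {  # tie-broken to the first maximal node
      sel <- which.max(f)
      w <- 1
    }
    d <- colSums(w * dirs[sel, , drop = FALSE]) / sum(w)
    d <- d / sqrt(sum(d^2))
    r <- sum(w * r_node[sel]) / sum(w)
    pos[ii, ] <- mesh$center + r * d
  }
  structure(data.frame(frame = keep, time = tt[keep], x = pos[, 1],
                       y = pos[, 2], z = pos[, 3],
                       contrast = contrast[keep]),
            class = c("domain_track", "data.frame"))
}

#' Decompose domain velocities into polar and azimuthal components
#'
#' Each step between consecutively tracked peaks is the straight-line (chord)
#' displacement divided by the elapsed time, in um/min. The displacement is
#' decomposed along the local polar (`e_theta`, toward increasing latitude)
#' and azimuthal (`e_phi`) unit tangents at the step midpoint; per-cell means
#' are taken over absolute component values. The speed anisotropy
#' `v_a = <v_phi>/<v_theta>` is unity for isotropic propagation; it is
#' flagged infinite (and excluded from population fits) when the polar
#' component vanishes. Steps whose midpoint falls on the polar axis, where
#' `e_phi` is undefined, are dropped.
#'
#' @param track a [track_domain()] result with at least 6 rows (5 steps).
#' @param mesh the matching [cell_mesh()].
#' @return list with `v_mean`, `v_theta`, `v_phi`, `v_a`, `v_a_defined`,
#'   `steps` (per-step data.frame with `time`, `v`, `v_theta`, `v_phi`).
#' @export
decompose_velocity <- function(track, mesh) {
  if (nrow(track) < 6) stop("need at least 5 tracked steps")
  cx <- mesh$center
  p <- as.matrix(track[, c("x", "y", "z")])
  dtim <- diff(track$time)
  rows <- list()
  for (i in seq_len(nrow(p) - 1)) {
    d <- p[i + 1, ] - p[i, ]
    m <- (p[i, ] + p[i + 1, ]) / 2 - cx
    m <- m / sqrt(sum(m^2))
    eph <- c(-m[2], m[1], 0)
    nph <- sqrt(sum(eph^2))
    if (nph < 1e-9) next
    eph <- eph / nph
    eth <- c(0, 0, 1) - m[3] * m
    eth <- eth / sqrt(sum(eth^2))
    fac <- 60 / dtim[i]  # um/s -> um/min
    rows[[length(rows) + 1]] <- data.frame(
      time = track$time[i],
      v = sqrt(sum(d^2)) * fac,
      v_theta = abs(sum(d * eth)) * fac,
      v_phi = abs(sum(d * eph)) * fac)
  }
  steps <- do.call(rbind, rows)
  if (is.null(steps) || nrow(steps) < 5) stop("need at least 5 tracked steps")
  v_theta <- mean(steps$v_theta)
  v_phi <- mean(steps$v_phi)
  defined <- v_theta > 1e-9
  list(v_mean = mean(steps$v), v_theta = v_theta, v_phi = v_phi,
       v_a = if (defined) v_phi / v_theta else Inf,
       v_a_defined = defined, steps = steps)
}

#' Population-level linear relations through the Delta-alpha axis
#'
#' Bins the per-cell table by `delta_alpha`, takes per-bin medians of
#' `delta_alpha`, `r_a` and `v_a`, fits each of `r_a` and `v_a` linearly
#' against the median `delta_alpha` (weighted by bin occupancy), and
#' eliminates `delta_alpha` to obtain the composed relation
#' `v_a = m * r_a + n_0`. Cells with undefined (infinite) `v_a` are excluded.
#'
#' @param cells data.frame with at least `delta_alpha`, `r_a`, `v_a`
#'   (>= 8 rows).
#' @param n_bins number of `delta_alpha` bins (default 6; at least 3 must be
#'   occupied).
#' @return A `population_fit`: list with `m`, `n0`, the two marginal fits
#'   (`ra_fit`, `va_fit`: intercept/slope pairs), `bins` (data.frame) and the
#'   filtered `cells` table.
#' @export
population_fits <- function(cells, n_bins = 6) {
  need <- c("delta_alpha", "r_a", "v_a")
  if (!all(need %in% names(cells))) {
    stop("cells must contain ", paste(need, collapse = ", "))
  }
  cells <- cells[is.finite(cells$v_a) & is.finite(cells$delta_alpha) &
                 is.finite(cells$r_a), , drop = FALSE]
  if (nrow(cells) < 8) stop("need at least 8 cells")
  rng <- range(cells$delta_alpha)
  if (diff(rng) <= 1e-6) stop("fit error: no spread in delta_alpha")
  breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1)
  bin <- cut(cells$delta_alpha, breaks, labels = FALSE)
  occ <- table(bin)
  if (length(occ) < 3) stop("fit error: fewer than 3 occupied delta_alpha bins")
  agg <- do.call(rbind, lapply(names(occ), function(b) {
    i <- bin == as.integer(b)
    data.frame(delta_alpha = stats::median(cells$delta_alpha[i]),
               r_a = stats::median(cells$r_a[i]),
               v_a = stats::median(cells$v_a[i]),
               n = sum(i))
  }))
  ra_fit <- stats::lm(r_a ~ delta_alpha, data = agg, weights = agg$n)
  va_fit <- stats::lm(v_a ~ delta_alpha, data = agg, weights = agg$n)
  a1 <- stats::coef(ra_fit)[2]; b1 <- stats::coef(ra_fit)[1]
  a2 <- stats::coef(va_fit)[2]; b2 <- stats::coef(va_fit)[1]
  if (!is.finite(a1) || abs(a1) < 1e-12) {
    stop("fit error: r_a does not vary with delta_alpha")
  }
  m <- unname(a2 / a1)
  n0 <- unname(b2 - a2 * b1 / a1)
  structure(list(m = m, n0 = n0,
                 ra_fit = stats::coef(ra_fit), va_fit = stats::coef(va_fit),
                 bins = agg, cells = cells),
            class = "population_fit")
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("population_fit: v_a = %.3f * r_a + %.3f  (%d cells, %d bins)\n",
              x$m, x$n0, nrow(x$cells), nrow(x$bins)))
  invisible(x)
}
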