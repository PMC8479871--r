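#' Specification of a synthetic cell scene
#'
#' Collects the geometric and dynamic parameters of a simulated
#' actin-inhibited cell: a sphere of radius `R` truncated by the substrate at
#' contact angle `Omega` (`Omega = 0` gives a full sphere, `Omega > 0` a
#' truncated sphere closed by a flat ventral disc of radius `R*sin(Omega)`),
#' carrying one of the prototypical membrane activity patterns observed on
#' such cells: waves circulating parallel to the contact perimeter
#' (`"horizontal_wave"`), waves periodically crossing it (`"vertical_wave"`),
#' transient spots (`"transient_spots"`), a spiral pinned at the contact
#' perimeter (`"pinned_spiral"`), pure noise (`"white_noise"`) or a constant
#' baseline (`"quiet"`).
#'
#' @param radius sphere radius R in micrometres.
#' @param omega contact angle in radians, in `[0, pi/2]`.
#' @param pattern one of `"horizontal_wave"`, `"vertical_wave"`,
#'   `"transient_spots"`, `"pinned_spiral"`, `"white_noise"`, `"quiet"`.
#' @param period oscillation/rotation period T in seconds (also the mean
#'   inter-birth time for `"transient_spots"`).
#' @param wave_width angular half-width of the activity domain (radians).
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (intensity units).
#' @param baseline baseline intensity.
#' @param duration recording length in seconds.
#' @param dt sampling interval in seconds (default 10).
#' @param seed integer seed governing all stochastic draws.
#' @param axis optional rotation axis (length-3) for wave patterns; defaults
#'   to the vertical axis for `"horizontal_wave"` and a horizontal axis for
#'   `"vertical_wave"`.
#' @param band_theta latitude of the circulating spot relative to the
#'   rotation axis' equator (radians, default 0: the spot travels a great
#'   circle; at `band_theta != 0` it travels the small circle of radius
#'   `R*cos(band_theta)`).
#' @param node_area target mean node area of the generated mesh (um^2).
#'
#' @return A `scene_spec` object (a validated list).
#' @export
scene_spec <- function(radius = 3, omega = pi / 3, pattern = "horizontal_wave",
                       period = 200, wave_width = 0.6, noise_sd = 0.1,
                       baseline = 1, duration = 1800, dt = 10, seed = 1,
                       axis = NULL, band_theta = 0, node_area = 0.3) {
  pattern <- match.arg(pattern, c("horizontal_wave", "vertical_wave",
                                  "transient_spots", "pinned_spiral",
                                  "white_noise", "quiet"))
  if (radius <= 0) stop("radius must be positive")
  if (omega < 0 || omega > pi / 2) stop("omega must lie in [0, pi/2]")
  if (dt <= 0 || duration < dt) stop("invalid duration/dt")
  if (period <= 0) stop("period must be positive")
  structure(list(radius = radius, omega = omega, pattern = pattern,
                 period = period, wave_width = wave_width,
                 noise_sd = noise_sd, baseline = baseline,
                 duration = duration, dt = dt, seed = as.integer(seed),
                 axis = axis, band_theta = band_theta, node_area = node_area),
            class = "scene_spec")
}

#' Generate the truncated-sphere membrane mesh of a synthetic cell
#'
#' Builds a closed triangulated surface: the part of a sphere of radius R
#' above the truncation plane at polar angle `theta_adh = -pi/2 + Omega`,
#' closed by a flat ventral disc of radius `R*sin(Omega)`. Free nodes carry
#' the geometric polar angle `theta = asin(z/R)`; ventral-disc nodes are
#' assigned `theta` linearly in their radial position, from `-pi/2` at the
#' disc centre to `theta_adh` at the rim, so that equal-area surface maps
#' cover the whole closed surface. Node density is chosen so the mean node
#' area is approximately `spec$node_area` (0.3 um^2 by default).
#'
#' @param spec a [scene_spec()].
#' @return A [cell_mesh()] with adherent flags, `theta_adh`, and node areas.
#' @export
make_geometry <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  R <- spec$radius
  Om <- spec$omega
  a0 <- spec$node_area
  if (Om < 1e-9) {
    n <- max(100L, round(4 * pi * R^2 / a0))
    nodes <- R * fibonacci_sphere(n)
    tri <- triangulate_directions(nodes)
    return(cell_mesh(nodes, tri, center = c(0, 0, 0), R_eff = R))
  }
  zc <- -R * cos(Om)           # truncation plane
  rr <- R * sin(Om)            # rim radius
  theta_adh <- -pi / 2 + Om
  h <- sqrt(2 * a0 / sqrt(3))  # hexagonal-lattice spacing at target area
  m_rim <- max(8L, round(2 * pi * rr / h))
  ang <- 2 * pi * (seq_len(m_rim) - 1) / m_rim
  rim <- cbind(rr * cos(ang), rr * sin(ang), zc)
  # ventral disc interior: sunflower layout with a margin to the rim
  r_in <- rr - 0.75 * h
  disc <- NULL
  if (r_in > 0.3 * h) {
    nd <- max(1L, round(pi * r_in^2 / a0))
    k <- seq_len(nd)
    rad <- r_in * sqrt((k - 0.5) / nd)
    ga <- pi * (3 - sqrt(5))
    disc <- cbind(rad * cos(ga * k), rad * sin(ga * k), zc)
  } else {
    disc <- matrix(c(0, 0, zc), 1, 3)
  }
  # free spherical part: Fibonacci lattice above the rim with a margin
  nfull <- max(100L, round(4 * pi * R^2 / a0))
  sph <- R * fibonacci_sphere(nfull)
  lat <- asin(pmin(1, pmax(-1, sph[, 3] / R)))
  sph <- sph[lat > theta_adh + 0.75 * h / R, , drop = FALSE]
  nodes <- rbind(sph, rim, disc)
  adherent <- c(rep(FALSE, nrow(sph)), rep(TRUE, m_rim + nrow(disc)))
  # triangulate about an interior point strictly above the disc plane: at
  # Omega = pi/2 the disc passes through the sphere centre, which therefore
  # cannot serve as the star-shape viewpoint
  view <- c(0, 0, (zc + R) / 2)
  tri <- triangulate_directions(sweep(nodes, 2, view))
  check_closed_surface(nodes, tri)
  rel <- nodes
  theta <- asin(pmin(1, pmax(-1, rel[, 3] / sqrt(rowSums(rel^2)))))
  rxy <- sqrt(nodes[, 1]^2 + nodes[, 2]^2)
  theta[adherent] <- -pi / 2 + (rxy[adherent] / rr) * Om
  phi <- atan2(nodes[, 2], nodes[, 1])
  # orientation comes from the triangulation viewpoint; validate = FALSE so
  # faces in the disc plane are not re-flipped about the sphere centre
  cell_mesh(nodes, tri, center = c(0, 0, 0), theta = theta, phi = phi,
            adherent = adherent, theta_adh = theta_adh, R_eff = R,
            validate = FALSE)
}

#' Per-node membrane signal time series
#'
#' A `signal_field` holds one intensity time series per mesh node, sampled at
#' interval `dt` starting at `t0`.
#'
#' @param values numeric matrix (nodes x time).
#' @param dt sampling interval in seconds.
#' @param t0 time of the first sample in seconds.
#' @return A `signal_field` object.
#' @export
signal_field <- function(values, dt, t0 = 0) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("signal contains missing values")
  structure(list(values = values, dt = dt, t0 = t0), class = "signal_field")
}

#' Time points of a signal field
#' @param signal a [signal_field()].
#' @export
signal_times <- function(signal) {
  signal$t0 + signal$dt * (seq_len(ncol(signal$values)) - 1)
}

#' @export
print.signal_field <- function(x, ...) {
  cat(sprintf("signal_field: %d nodes x %d time points, dt = %g s\n",
              nrow(x$values), ncol(x$values), x$dt))
  invisible(x)
}

#' Synthesize a membrane activity pattern on a mesh
#'
#' Generates per-node time series `baseline + pattern activity + noise` for
#' the pattern named in the scene specification, together with the realised
#' ground truth (rotation axis, spot birth table, prescribed phase field and
#' noiseless activity) needed to validate downstream analyses. The Gaussian
#' noise is drawn per node from a seed derived from `spec$seed` and the node
#' index, so the field is reproducible bit-for-bit and individual node series
#' do not depend on mesh size.
#'
#' Wave domains are modelled as a Gaussian-profile activity spot whose centre
#' rotates with period T about the vertical axis (`horizontal_wave`, at the
#' equator, parallel to the contact perimeter) or a horizontal axis
#' (`vertical_wave`, crossing the contact perimeter twice per cycle).
#' `transient_spots` draws spot birth times from a Poisson process (mean
#' inter-birth time T) at uniform positions above the contact perimeter, each
#' with a fixed lifetime and an exponential-shoulder temporal profile.
#' `pinned_spiral` prescribes the phase field of a spiral whose singularity
#' sits on the contact perimeter, with the topologically required
#' counter-rotating singularity at the antipode.
#'
#' @param mesh a [cell_mesh()] from [make_geometry()].
#' @param spec the [scene_spec()] used for the mesh.
#' @return A list with elements `signal` (a [signal_field()]) and
#'   `ground_truth` (a list; see Details).
#' @export
make_signal <- function(mesh, spec) {
  stopifnot(inherits(mesh, "cell_mesh"), inherits(spec, "scene_spec"))
  tt <- seq(0, spec$duration - spec$dt, by = spec$dt)
  nt <- length(tt)
  n <- nrow(mesh$nodes)
  dirs <- normalize_rows(sweep(mesh$nodes, 2, mesh$center))
  gt <- list(pattern = spec$pattern, theta_adh = mesh$theta_adh,
             period = spec$period)

  act <- switch(spec$pattern,
    quiet = matrix(0, n, nt),
    white_noise = matrix(0, n, nt),
    horizontal_wave = ,
    vertical_wave = {
      axis <- spec$axis
      if (is.null(axis)) {
        axis <- if (spec$pattern == "horizontal_wave") c(0, 0, 1) else c(0, 1, 0)
      }
      axis <- axis / sqrt(sum(axis^2))
      gt$axis <- axis
      gt$band_theta <- spec$band_theta
      gt$angular_speed <- 2 * pi / spec$period
      rotating_spot_activity(dirs, axis, spec$period, spec$wave_width, tt,
                             spec$band_theta)
    },
    transient_spots = {
      if (is.null(mesh$theta_adh) || is.na(mesh$theta_adh)) {
        th_lo <- -pi / 2
      } else th_lo <- mesh$theta_adh
      set.seed(spec$seed)
      births <- cumsum(stats::rexp(ceiling(4 * spec$duration / spec$period),
                                   rate = 1 / spec$period))
      births <- births[births < spec$duration]
      lifetime <- spec$period / 2
      pos <- matrix(0, length(births), 3)
      for (k in seq_along(births)) {
        repeat {
          p <- stats::rnorm(3)
          p <- p / sqrt(sum(p^2))
          if (asin(p[3]) > th_lo) break
        }
        pos[k, ] <- p
      }
      gt$spots <- data.frame(birth = births, lifetime = lifetime,
                             x = pos[, 1], y = pos[, 2], z = pos[, 3])
      spot_activity(dirs, births, pos, lifetime, spec$wave_width, tt)
    },
    pinned_spiral = {
      if (is.null(mesh$theta_adh) || is.na(mesh$theta_adh) ||
          !any(mesh$adherent)) {
        stop("pinned_spiral requires a cell with a contact perimeter (omega > 0)")
      }
      # singularity on the contact perimeter at phi = 0
      a <- c(cos(mesh$theta_adh), 0, sin(mesh$theta_adh))
      gt$singularity <- a * mesh$R_eff
      gt$counter_singularity <- -a * mesh$R_eff
      sp <- spiral_phase_field(dirs, a)
      gt$phase <- sp$chi
      env <- sin(sp$d)
      outer(env, rep(1, nt)) *
        cos(outer(sp$chi, rep(1, nt)) - outer(rep(1, n), 2 * pi * tt / spec$period))
    }
  )
  gt$activity <- act
  noise <- matrix(0, n, nt)
  if (spec$noise_sd > 0) {
    for (i in seq_len(n)) {
      set.seed(node_seed(spec$seed, i))
      noise[i, ] <- stats::rnorm(nt, sd = spec$noise_sd)
    }
  }
  sig <- signal_field(spec$baseline + act + noise, dt = spec$dt, t0 = 0)
  list(signal = sig, ground_truth = gt)
}

# Deterministic per-node seed below 2^31 (counter-based scheme).
node_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 9973) %% 2147483629
}

# Gaussian activity spot whose centre rotates on the great circle
# perpendicular to `axis`; at t = 0 the spot peak lies in the plane spanned
# by the first basis vector (peak-at-origin convention).
rotating_spot_activity <- function(dirs, axis, period, width, tt,
                                   band_theta = 0) {
  e1 <- if (abs(axis[3]) < 0.9) c(-axis[2], axis[1], 0) else c(1, 0, 0)
  e1 <- e1 - sum(e1 * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  n <- nrow(dirs)
  act <- matrix(0, n, length(tt))
  for (j in seq_along(tt)) {
    psi <- 2 * pi * tt[j] / period
    u <- cos(band_theta) * (cos(psi) * e1 + sin(psi) * e2) +
      sin(band_theta) * axis
    d <- acos(pmin(1, pmax(-1, dirs %*% u)))
    act[, j] <- exp(-d^2 / (2 * width^2))
  }
  act
}

spot_activity <- function(dirs, births, pos, lifetime, width, tt) {
  n <- nrow(dirs)
  act <- matrix(0, n, length(tt))
  if (length(births) == 0) return(act)
  tau_r <- lifetime / 3
  for (k in seq_along(births)) {
    d <- acos(pmin(1, pmax(-1, dirs %*% pos[k, ])))
    sp <- exp(-d^2 / (2 * width^2))
    u <- tt - births[k]
    live <- u >= 0 & u <= lifetime
    if (!any(live)) next
    prof <- (u[live] / tau_r) * exp(1 - u[live] / tau_r)
    act[, live] <- act[, live] + outer(as.numeric(sp), prof)
  }
  act
}

# Archimedean-like spiral phase about the axis through the pinned singularity
# `a` and its antipode: chi = azimuth about a + polar distance from a.
spiral_phase_field <- function(dirs, a) {
  e1 <- if (abs(a[3]) < 0.9) c(-a[2], a[1], 0) else c(1, 0, 0)
  e1 <- e1 - sum(e1 * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  eta <- atan2(dirs %*% e2, dirs %*% e1)
  d <- acos(pmin(1, pmax(-1, dirs %*% a)))
  list(chi = as.numeric((eta + d) %% (2 * pi)), d = as.numeric(d))
}
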