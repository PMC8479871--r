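#' Detect phase singularities on the mesh at one time point
#'
#' For every triangular face the winding number of the phase around its
#' oriented vertex loop is computed by summing the three phase differences,
#' each wrapped to `(-pi, pi]`; faces where the sum is `+/- 2*pi` contain a
#' phase singularity of topological charge `+/- 1` (the rotation centre of a
#' spiral wave). On a closed surface the charges necessarily sum to zero.
#' Faces in quiescent regions -- a majority of their nodes below the
#' amplitude guard -- are skipped when `amp_guard` is set; a single
#' low-amplitude node does not disqualify a face, because the core of a
#' genuine spiral is itself an amplitude zero.
#'
#' @param pmap a [phase_map()], or a numeric per-node phase vector.
#' @param mesh the matching [cell_mesh()].
#' @param t_index time index into the phase map (ignored for a phase vector).
#' @param amp_guard exclude faces with low-amplitude nodes (default `TRUE`).
#' @param coi_guard skip the frame entirely when it lies inside the wavelet
#'   cone of influence at the cell's dominant scale (default `TRUE`;
#'   boundary-affected phase estimates mislocate spiral cores).
#' @return data.frame with columns `face`, `x`, `y`, `z` (face centroid),
#'   `charge`; zero rows when no singularity is present.
#' @export
find_singularities <- function(pmap, mesh, t_index = 1, amp_guard = TRUE,
                               coi_guard = TRUE) {
  if (inherits(pmap, "phase_map")) {
    phase <- pmap$phase[, t_index]
    valid <- !is.na(phase)
    low <- if (amp_guard) pmap$low_amp else rep(FALSE, length(phase))
    if (coi_guard) {
      conf <- if (any(!pmap$low_amp)) !pmap$low_amp else rep(TRUE, nrow(pmap$phase))
      s_dom <- stats::median(pmap$period[conf, t_index])
      if (pmap$time[t_index] < sqrt(2) * s_dom) {
        return(data.frame(face = integer(0), x = numeric(0), y = numeric(0),
                          z = numeric(0), charge = numeric(0)))
      }
    }
  } else {
    phase <- as.numeric(pmap)
    valid <- !is.na(phase)
    low <- rep(FALSE, length(phase))
  }
  if (mean(!is.na(phase)) < 0.95) {
    warning("phase defined on fewer than 95% of nodes")
  }
  tr <- mesh$triangles
  ok <- valid[tr[, 1]] & valid[tr[, 2]] & valid[tr[, 3]] &
    (low[tr[, 1]] + low[tr[, 2]] + low[tr[, 3]] <= 1)
  wrap <- function(d) d - 2 * pi * ceiling(d / (2 * pi) - 0.5)  # to (-pi, pi]
  w <- wrap(phase[tr[, 2]] - phase[tr[, 1]]) +
       wrap(phase[tr[, 3]] - phase[tr[, 2]]) +
       wrap(phase[tr[, 1]] - phase[tr[, 3]])
  charge <- round(w / (2 * pi))
  hit <- which(ok & charge != 0)
  cen <- (mesh$nodes[tr[hit, 1], , drop = FALSE] +
          mesh$nodes[tr[hit, 2], , drop = FALSE] +
          mesh$nodes[tr[hit, 3], , drop = FALSE]) / 3
  data.frame(face = hit,
             x = cen[, 1], y = cen[, 2], z = cen[, 3],
             charge = charge[hit])
}

#' Contact-perimeter ring nodes
#'
#' Adherent nodes adjacent to at least one free node; empty for a cell
#' without an adhered patch.
#' @param mesh a [cell_mesh()].
#' @return integer node indices.
#' @export
perimeter_ring <- function(mesh) {
  if (!any(mesh$adherent)) return(integer(0))
  nb <- vertex_neighbors(mesh)
  which(mesh$adherent & vapply(seq_along(nb), function(i) {
    any(!mesh$adherent[nb[[i]]])
  }, logical(1)))
}

#' Track phase singularities and classify pinning
#'
#' Links per-frame singularity lists into tracks by greedy nearest-neighbour
#' matching (closest pairs first, distance gate `2 * pin_dist` per frame,
#' matching charges); a missed frame terminates a track (no gap bridging).
#' Tracks shorter than `min_lifetime` frames are discarded as flicker. A
#' track is classified *pinned* when at least `pin_frac` of its lifetime lies
#' within `pin_dist` of the contact-perimeter ring, otherwise *free*.
#'
#' @param sing_list list of [find_singularities()] frames at consecutive
#'   times (at least 5).
#' @param mesh the matching [cell_mesh()].
#' @param pin_dist pinning distance in micrometres (default 1).
#' @param pin_frac minimum pinned fraction of lifetime (default 0.8).
#' @param min_lifetime minimum track length in frames (default 3).
#' @return data.frame with one row per track: `track_id`, `first_frame`,
#'   `lifetime`, `charge`, `mean_dist_perimeter`, `pinned`, plus a
#'   `"points"` attribute holding the per-frame positions
#'   (`track_id`, `frame`, `x`, `y`, `z`, `charge`, `dist_perimeter`).
#' @export
track_singularities <- function(sing_list, mesh, pin_dist = 1,
                                pin_frac = 0.8, min_lifetime = 3) {
  if (length(sing_list) < 5) stop("need singularities at >= 5 consecutive times")
  ring <- perimeter_ring(mesh)
  ring_pos <- mesh$nodes[ring, , drop = FALSE]
  perim_dist <- function(p) {
    if (length(ring) == 0) return(Inf)
    min(sqrt(rowSums(sweep(ring_pos, 2, p)^2)))
  }
  gate <- 2 * pin_dist
  tracks <- list()    # each: list(frames, pos (k x 3), charge, open)
  active <- integer(0)
  for (f in seq_along(sing_list)) {
    s <- sing_list[[f]]
    pts <- if (nrow(s)) cbind(s$x, s$y, s$z) else matrix(0, 0, 3)
    used <- rep(FALSE, nrow(s))
    matched_tracks <- integer(0)
    if (length(active) && nrow(s)) {
      last <- t(vapply(tracks[active], function(tr) tr$pos[nrow(tr$pos), ],
                       numeric(3)))
      D <- outer(seq_len(nrow(last)), seq_len(nrow(s)),
                 Vectorize(function(i, j) sqrt(sum((last[i, ] - pts[j, ])^2))))
      ch_ok <- outer(vapply(tracks[active], `[[`, numeric(1), "charge"),
                     s$charge, "==")
      D[!ch_ok] <- Inf
      repeat {
        m <- which.min(D)
        if (!length(m) || D[m] > gate) break
        i <- (m - 1) %% nrow(D) + 1
        j <- (m - 1) %/% nrow(D) + 1
        tid <- active[i]
        tracks[[tid]]$frames <- c(tracks[[tid]]$frames, f)
        tracks[[tid]]$pos <- rbind(tracks[[tid]]$pos, pts[j, ])
        used[j] <- TRUE
        matched_tracks <- c(matched_tracks, tid)
        D[i, ] <- Inf
        D[, j] <- Inf
      }
    }
    for (j in which(!used)) {
      tracks[[length(tracks) + 1]] <- list(frames = f,
                                           pos = matrix(pts[j, ], 1, 3),
                                           charge = s$charge[j])
      matched_tracks <- c(matched_tracks, length(tracks))
    }
    active <- matched_tracks  # unmatched active tracks are closed
  }
  keep <- which(vapply(tracks, function(tr) length(tr$frames),
                       integer(1)) >= min_lifetime)
  rows <- list(); pts_rows <- list()
  for (ii in seq_along(keep)) {
    tr <- tracks[[keep[ii]]]
    # rolling-median smoothing (5 frames) suppresses the face-size
    # quantisation jitter of the winding detector before distances are taken
    sm <- apply(tr$pos, 2, stats::runmed,
                k = min(5, 2 * ((nrow(tr$pos) - 1) %/% 2) + 1))
    sm <- matrix(sm, ncol = 3)
    d <- apply(sm, 1, perim_dist)
    rows[[ii]] <- data.frame(
      track_id = ii, first_frame = tr$frames[1],
      lifetime = length(tr$frames), charge = tr$charge,
      mean_dist_perimeter = mean(d),
      pinned = is.finite(d[1]) && mean(d <= pin_dist) >= pin_frac)
    pts_rows[[ii]] <- data.frame(track_id = ii, frame = tr$frames,
                                 x = tr$pos[, 1], y = tr$pos[, 2],
                                 z = tr$pos[, 3], charge = tr$charge,
                                 dist_perimeter = d)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(0), first_frame = integer(0),
               lifetime = integer(0), charge = numeric(0),
               mean_dist_perimeter = numeric(0), pinned = logical(0))
  attr(out, "points") <- if (length(pts_rows)) do.call(rbind, pts_rows) else
    data.frame()
  out
}

#' Detect wave-front guidance along the contact perimeter
#'
#' A frame shows *guidance* when the wave front (nodes with phase within
#' `front_tol` of `2*pi`) near the contact perimeter runs parallel to it:
#' the principal axis of the front-node positions is aligned with the local
#' azimuthal direction to within `max_angle`. Guidance events are runs of at
#' least `min_frames` consecutive guided frames.
#'
#' @param pmap a [phase_map()].
#' @param mesh the matching [cell_mesh()].
#' @param band distance band around the perimeter in micrometres (default 2).
#' @param front_tol phase tolerance for front membership (radians, default
#'   0.6).
#' @param max_angle maximal front/perimeter angle in degrees (default 20).
#' @param min_frames minimal run length (default 3).
#' @param min_nodes minimal front nodes per frame (default 5).
#' @return list with logical `guided` per frame and data.frame `events`
#'   (`start`, `end`, `length`).
#' @export
detect_guidance <- function(pmap, mesh, band = 2, front_tol = 0.6,
                            max_angle = 20, min_frames = 3, min_nodes = 5) {
  ring <- perimeter_ring(mesh)
  nt <- ncol(pmap$phase)
  guided <- rep(FALSE, nt)
  if (length(ring)) {
    ring_pos <- mesh$nodes[ring, , drop = FALSE]
    dmin <- apply(mesh$nodes, 1, function(p) {
      min(sqrt(rowSums(sweep(ring_pos, 2, p)^2)))
    })
    near <- dmin <= band & !pmap$low_amp
    for (f in seq_len(nt)) {
      ph <- pmap$phase[, f]
      front <- which(near & !is.na(ph) & (ph > 2 * pi - front_tol))
      if (length(front) < min_nodes) next
      P <- mesh$nodes[front, , drop = FALSE]
      P <- sweep(P, 2, colMeans(P))
      ax <- svd(P)$v[, 1]
      m <- colMeans(mesh$nodes[front, , drop = FALSE]) - mesh$center
      eph <- c(-m[2], m[1], 0)
      if (sqrt(sum(eph^2)) < 1e-9) next
      eph <- eph / sqrt(sum(eph^2))
      ang <- acos(min(1, abs(sum(ax * eph)))) * 180 / pi
      guided[f] <- ang < max_angle
    }
  }
  r <- rle(guided)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev <- which(r$values & r$lengths >= min_frames)
  list(guided = guided,
       events = data.frame(start = starts[ev], end = ends[ev],
                           length = r$lengths[ev]))
}
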