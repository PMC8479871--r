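test_that("the transform localises pure and mixed oscillations on the scale axis", {
  tt <- (0:179) * 10
  tr <- morlet_transform(cos(2 * pi * tt / 200), 10)
  prof <- rowMeans(Mod(tr$coef)[, 60:120])
  best <- tr$scales[which.max(prof)]
  step <- exp(log(600 / 60) / 39)
  expect_lt(abs(log(best / 200)), log(step) * 1.01)
  # constant series: zero coefficients
  tr0 <- morlet_transform(rep(2, 60), 10)
  expect_lt(max(Mod(tr0$coef)), 1e-10)
  # two components appear as two local amplitude maxima
  tr2 <- morlet_transform(cos(2 * pi * tt / 150) + cos(2 * pi * tt / 300), 10)
  p2 <- rowMeans(Mod(tr2$coef)[, 80:100])
  loc <- which(diff(sign(diff(p2))) == -2) + 1
  peaks <- tr2$scales[loc]
  expect_true(any(abs(log(peaks / 150)) < log(step) * 1.5))
  expect_true(any(abs(log(peaks / 300)) < log(step) * 1.5))
})

test_that("ridge phase advances by 2*pi per period and ties pick the lower frequency", {
  tt <- (0:179) * 10
  tr <- morlet_transform(cos(2 * pi * tt / 200), 10)
  rp <- ridge_phase(tr)
  mid <- 60:120
  dph <- diff(rp$phase[mid])
  dph <- (dph + pi) %% (2 * pi) - pi
  expect_equal(median(dph), 2 * pi * 10 / 200, tolerance = 0.05)
  expect_lt(abs(median(rp$period[mid]) - 200) / 200, 0.06)
  # intensity peak maps to phase 2*pi
  peak_t <- mid[which.max(cos(2 * pi * tt[mid] / 200))]
  expect_lt(min(abs(rp$phase[peak_t] - 2 * pi), rp$phase[peak_t]), 0.5)
  # amplitude ties resolve toward the lower frequency (larger period):
  # scales are scanned from the largest period with strict improvement
  cfg <- wavelet_config()
  expect_true(all(diff(cfg$scales) < 0))
})

test_that("phase maps recover the rotation of a horizontal wave", {
  mesh <- truncated_mesh()
  spec <- scene_spec(radius = 3, omega = pi / 3, pattern = "horizontal_wave",
                     period = 200, noise_sd = 0.02, duration = 900, seed = 2)
  gen <- make_signal(mesh, spec)
  pm <- phase_map(gen$signal, mesh, wavelet_config(t_min = 300, t_max = 800))
  band <- which(abs(mesh$theta) < 0.3 & !pm$low_amp)
  expect_gt(length(band), 20)
  # per-node dominant period near T
  expect_lt(abs(median(pm$period[band, ]) - 200) / 200, 0.06)
  # isophase structure: phase at band nodes tracks the azimuth, so the
  # circular correlation between phase and phi is strong
  j <- ncol(pm$phase) %/% 2
  ph <- pm$phase[band, j]
  # the front arrives later at larger phi, so phase falls linearly with
  # azimuth: phase + phi is circularly concentrated
  ccor <- abs(mean(exp(1i * (ph + mesh$phi[band]))))
  expect_gt(ccor, 0.8)
  # and the wave front rotates: phase at a fixed node advances 2pi/T per s
  dph <- diff(pm$phase[band[1], ])
  dph <- (dph + pi) %% (2 * pi) - pi
  expect_equal(median(dph) / spec$dt, 2 * pi / 200, tolerance = 0.1)
})

test_that("period recovery holds across the 2-5 min band at >= 95% of active nodes", {
  mesh <- truncated_mesh()
  step <- exp(log(600 / 60) / 39)
  for (T in c(120, 200, 300)) {
    spec <- scene_spec(radius = 3, omega = pi / 3, pattern = "horizontal_wave",
                       period = T, noise_sd = 0, duration = 1200, seed = 3)
    gen <- make_signal(mesh, spec)
    pm <- phase_map(gen$signal, mesh,
                    wavelet_config(t_min = 450, t_max = 1100))
    active <- which(!pm$low_amp &
                    apply(gen$ground_truth$activity, 1, max) > 0.2)
    ok <- abs(log(pm$period[active, ] / T)) < log(step) * 1.5
    expect_gt(mean(ok), 0.95)
  }
})

test_that("a quiet scene yields an undefined (flagged) phase map", {
  mesh <- sphere_mesh()
  sig <- signal_field(matrix(5, nrow(mesh$nodes), 100), dt = 10)
  pm <- phase_map(sig, mesh)
  expect_true(all(is.na(pm$phase)))
})

test_that("uniform phase fields contain no singularities", {
  mesh <- truncated_mesh()
  s <- find_singularities(rep(1.3, nrow(mesh$nodes)), mesh)
  expect_equal(nrow(s), 0)
})

test_that("two prescribed spiral pairs give four singularities of zero net charge", {
  mesh <- sphere_mesh()
  dirs <- memwave:::normalize_rows(mesh$nodes)
  azimuth_about <- function(a) {
    e1 <- if (abs(a[3]) < 0.9) c(-a[2], a[1], 0) else c(1, 0, 0)
    e1 <- e1 - sum(e1 * a) * a
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
            a[1] * e1[2] - a[2] * e1[1])
    atan2(dirs %*% e2, dirs %*% e1)
  }
  ph <- (azimuth_about(c(0, 0, 1)) + azimuth_about(c(1, 0, 0))) %% (2 * pi)
  s <- find_singularities(as.numeric(ph), mesh)
  expect_equal(nrow(s), 4)
  expect_equal(sum(s$charge), 0)
  # brute-force winding over all faces agrees with the detector
  tr <- mesh$triangles
  wrap <- function(d) d - 2 * pi * round(d / (2 * pi))
  w <- wrap(ph[tr[, 2]] - ph[tr[, 1]]) + wrap(ph[tr[, 3]] - ph[tr[, 2]]) +
    wrap(ph[tr[, 1]] - ph[tr[, 3]])
  expect_equal(sort(which(abs(w) > pi)), sort(s$face))
})

test_that("net topological charge vanishes on every closed-mesh frame", {
  sc <- spiral_case()
  for (t in seq(1, length(sc$pm$time), by = 5)) {
    s <- find_singularities(sc$pm, sc$mesh, t, amp_guard = FALSE,
                            coi_guard = FALSE)
    expect_equal(sum(s$charge), 0)
  }
})

test_that("the pinned spiral is tracked, classified pinned, and localised", {
  sc <- spiral_case()
  sings <- lapply(seq_along(sc$pm$time), function(t) {
    find_singularities(sc$pm, sc$mesh, t)
  })
  tracks <- track_singularities(sings, sc$mesh)
  expect_gt(nrow(tracks), 0)
  rim <- tracks[tracks$mean_dist_perimeter < 1.5, , drop = FALSE]
  far <- tracks[tracks$mean_dist_perimeter > 2, , drop = FALSE]
  # the long-lived perimeter track is pinned, all distant tracks are free
  main_rim <- rim[which.max(rim$lifetime), ]
  expect_true(main_rim$pinned)
  expect_gt(nrow(far), 0)
  expect_false(any(far$pinned))
  # localisation: singular faces near the prescribed core position
  pts <- attr(tracks, "points")
  rim_pts <- pts[pts$track_id == main_rim$track_id, ]
  gt <- sc$gen$ground_truth$singularity
  d <- sqrt((rim_pts$x - gt[1])^2 + (rim_pts$y - gt[2])^2 +
            (rim_pts$z - gt[3])^2)
  expect_lt(median(d), 2 * mean_edge_length(sc$mesh))
})

test_that("a two-frame flicker pair is rejected by the lifetime filter", {
  mesh <- truncated_mesh()
  mk <- function(x) data.frame(face = 1, x = x, y = 0, z = 0, charge = 1)
  empty <- data.frame(face = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), charge = numeric(0))
  frames <- list(mk(0), mk(0.1), empty, empty, empty, empty)
  tracks <- track_singularities(frames, mesh)
  expect_equal(nrow(tracks), 0)
})

test_that("a horizontal wave produces no pinned tracks", {
  mesh <- truncated_mesh()
  spec <- scene_spec(radius = 3, omega = pi / 3, pattern = "horizontal_wave",
                     period = 200, noise_sd = 0.05, duration = 1200, seed = 5)
  gen <- make_signal(mesh, spec)
  pm <- phase_map(gen$signal, mesh, wavelet_config(t_min = 400, t_max = 1100))
  sings <- lapply(seq_along(pm$time), function(t) {
    find_singularities(pm, mesh, t)
  })
  tracks <- track_singularities(sings, mesh)
  if (nrow(tracks) > 0) expect_false(any(tracks$pinned))
})
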