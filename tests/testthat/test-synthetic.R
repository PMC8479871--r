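test_that("full-sphere geometry matches the closed sphere", {
  mesh <- sphere_mesh()
  expect_equal(adherent_area(mesh), 0)
  expect_false(any(mesh$adherent))
  expect_true(is.na(mesh$theta_adh))
  expect_lt(abs(mesh_area(mesh) - 4 * pi * 9) / (4 * pi * 9), 0.02)
})

test_that("hemisphere-on-disc geometry has the analytic ventral area", {
  mesh <- make_geometry(scene_spec(radius = 3, omega = pi / 2))
  expect_lt(abs(adherent_area(mesh) - pi * 9) / (pi * 9), 0.02)
  expect_equal(mesh$theta_adh, 0)
  expect_equal(euler_characteristic(mesh), 2)
})

test_that("truncated-sphere area ratio converges to the exact value", {
  # area ratio against the closed-form cap/disc areas, R >= 2, 0.3 um^2 nodes
  for (case in list(c(2, pi / 3), c(3, pi / 4))) {
    R <- case[1]; Om <- case[2]
    mesh <- make_geometry(scene_spec(radius = R, omega = Om))
    A_disc <- pi * R^2 * sin(Om)^2
    A_exact <- 2 * pi * R^2 * (1 + cos(Om)) + A_disc
    expect_lt(abs(mesh_area(mesh) - A_exact) / A_exact, 0.02)
    r_a_mesh <- adherent_area(mesh) / mesh_area(mesh)
    expect_lt(abs(r_a_mesh - A_disc / A_exact) / (A_disc / A_exact), 0.01)
  }
})

test_that("ventral-disc nodes span theta from -pi/2 to theta_adh", {
  mesh <- truncated_mesh()
  th_adh <- -pi / 2 + pi / 3
  expect_equal(mesh$theta_adh, th_adh)
  expect_true(all(mesh$theta[mesh$adherent] >= -pi / 2 - 1e-9))
  expect_true(all(mesh$theta[mesh$adherent] <= th_adh + 1e-9))
  expect_true(all(mesh$theta[!mesh$adherent] > th_adh))
})

test_that("white-noise scenes are i.i.d. around the baseline", {
  mesh <- sphere_mesh()
  spec <- scene_spec(radius = 3, omega = 0, pattern = "white_noise",
                     noise_sd = 1, baseline = 2, duration = 3000, seed = 9)
  gen <- make_signal(mesh, spec)
  v <- gen$signal$values
  expect_lt(abs(mean(v) - 2), 0.05)
  expect_lt(abs(sd(as.numeric(v)) - 1), 0.05)
  lag1 <- apply(v[1:50, ], 1, function(x) cor(x[-1], x[-length(x)]))
  expect_lt(abs(mean(lag1)), 0.1)
})

test_that("wave patterns are periodic with period T at every active node", {
  mesh <- truncated_mesh()
  for (pattern in c("horizontal_wave", "vertical_wave")) {
    spec <- scene_spec(radius = 3, omega = pi / 3, pattern = pattern,
                       period = 200, noise_sd = 0, duration = 800, seed = 1)
    gen <- make_signal(mesh, spec)
    v <- gen$signal$values
    shift <- 200 / spec$dt
    expect_equal(v[, 1:(ncol(v) - shift)], v[, (shift + 1):ncol(v)],
                 tolerance = 1e-9)
    # dominant Fourier period within one sample of T at active nodes
    act <- gen$ground_truth$activity
    active <- which(apply(act, 1, function(x) diff(range(x))) > 0.3)
    nt <- ncol(v)
    freqs <- seq_len(nt %/% 2) / (nt * spec$dt)
    per <- vapply(active, function(i) {
      sp <- Mod(fft(act[i, ] - mean(act[i, ])))[2:(nt %/% 2 + 1)]
      1 / freqs[which.max(sp)]
    }, numeric(1))
    expect_true(all(abs(per - 200) <= spec$dt))
  }
})

test_that("the prescribed spiral phase winds by +/- 2pi around its singularities", {
  mesh <- truncated_mesh()
  spec <- scene_spec(radius = 3, omega = pi / 3, pattern = "pinned_spiral",
                     period = 120, noise_sd = 0, duration = 600, seed = 2)
  gen <- make_signal(mesh, spec)
  s <- find_singularities(gen$ground_truth$phase, mesh)
  expect_equal(nrow(s), 2)
  expect_equal(sum(s$charge), 0)
  expect_setequal(s$charge, c(-1, 1))
  # the pinned one lies at the prescribed perimeter position
  d <- sqrt((s$x - gen$ground_truth$singularity[1])^2 +
            (s$y - gen$ground_truth$singularity[2])^2 +
            (s$z - gen$ground_truth$singularity[3])^2)
  expect_lt(min(d), 2 * mean_edge_length(mesh))
})

test_that("pinned_spiral on a full sphere is a configuration error", {
  mesh <- sphere_mesh()
  spec <- scene_spec(radius = 3, omega = 0, pattern = "pinned_spiral")
  expect_error(make_signal(mesh, spec), "contact perimeter")
})

test_that("transient spots stay above the contact perimeter", {
  mesh <- truncated_mesh()
  spec <- scene_spec(radius = 3, omega = pi / 3, pattern = "transient_spots",
                     period = 150, noise_sd = 0, duration = 1200, seed = 3)
  gen <- make_signal(mesh, spec)
  spots <- gen$ground_truth$spots
  expect_gt(nrow(spots), 2)
  expect_true(all(asin(spots$z) > mesh$theta_adh))
  expect_true(all(spots$birth >= 0 & spots$birth < 1200))
})

test_that("identical scene specifications reproduce bit-identical signals", {
  mesh <- truncated_mesh()
  spec <- scene_spec(radius = 3, omega = pi / 3, pattern = "horizontal_wave",
                     noise_sd = 0.2, duration = 400, seed = 11)
  g1 <- make_signal(mesh, spec)
  g2 <- make_signal(mesh, spec)
  expect_identical(g1$signal$values, g2$signal$values)
  g3 <- make_signal(mesh, scene_spec(radius = 3, omega = pi / 3,
                                     pattern = "horizontal_wave",
                                     noise_sd = 0.2, duration = 400,
                                     seed = 12))
  expect_false(identical(g1$signal$values, g3$signal$values))
})

test_that("scene specification validates its domain", {
  expect_error(scene_spec(omega = 2), "omega")
  expect_error(scene_spec(radius = -1), "radius")
  expect_error(scene_spec(period = 0), "period")
})
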