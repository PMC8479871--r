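test_that("the area-ratio model evaluates its closed-form anchors", {
  expect_equal(area_ratio(0), 0)
  expect_equal(area_ratio(pi / 2), 1 / 3)
  expect_equal(area_ratio(pi / 6), 0.25 / (4 - (1 - sqrt(3) / 2)),
               tolerance = 1e-12)
  om <- seq(0, pi / 2, length.out = 50)
  expect_true(all(diff(area_ratio(om)) > 0))  # strictly increasing
  expect_error(area_ratio(2), "omega")
})

test_that("contact-angle inversion agrees with a bisection oracle and the closed form", {
  expect_equal(contact_angle(0), 0, tolerance = 1e-9)
  expect_equal(contact_angle(1 / 3), pi / 2, tolerance = 1e-8)
  # r_a = 0.1 against an independent fine bisection on the model itself
  f <- function(om) sin(om)^2 / (3 + cos(om)) - 0.1
  lo <- 0; hi <- pi / 2
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  expect_equal(contact_angle(0.1), (lo + hi) / 2, tolerance = 1e-8)
  r <- seq(0, 1 / 3, length.out = 40)
  expect_lt(max(abs(contact_angle(r) - contact_angle_closed_form(r))), 1e-7)
  expect_error(contact_angle(0.5), "r_a")
})

test_that("contact_angle undoes area_ratio across the whole branch", {
  om <- seq(0, pi / 2, length.out = 60)
  back <- contact_angle(area_ratio(om))
  expect_lt(max(abs(back - om)), 1e-8)
})

test_that("the model ratio deviates from the exact truncated-sphere ratio by at most ~7%", {
  om <- seq(0.01, pi / 2, length.out = 500)
  rel <- area_ratio(om) / area_ratio_exact(om) - 1
  # anchors agree exactly
  expect_equal(area_ratio(pi / 2), area_ratio_exact(pi / 2), tolerance = 1e-12)
  # interior discrepancy is real, bounded, and maximal near Omega ~ 62 deg
  expect_gt(max(rel), 0.07)
  expect_lt(max(rel), 0.075)
  expect_lt(abs(om[which.max(rel)] - acos(sqrt(12) - 3)), 0.02)
})

test_that("shape descriptors reproduce closed-form sphere values", {
  spec <- scene_spec(radius = 3.05, omega = 0)
  mesh <- make_geometry(spec)
  geo <- shape_descriptors(mesh)
  V_true <- 4 / 3 * pi * 3.05^3 * 1e-3  # pL
  expect_lt(abs(geo$V_pL - V_true) / V_true, 0.03)
  expect_lt(abs(geo$V_pL - 0.119) / 0.119, 0.05)
  expect_equal(geo$omega, 0)
  expect_true(is.na(geo$kappa_max))  # no contact perimeter
})

test_that("shape descriptors recover the contact angle of a synthetic cell", {
  mesh <- truncated_mesh()
  geo <- shape_descriptors(mesh)
  # the model inversion of the exact mesh ratio carries a known ~2.8 deg
  # offset at Omega = 60 deg; recovery stays within +/- 5 deg
  expect_lt(abs(geo$omega - pi / 3), 5 * pi / 180)
  expect_gt(geo$kappa_max, 1 / 3)  # perimeter is the high-curvature ring
  expect_equal(geo$r_a, adherent_area(mesh) / mesh_area(mesh))
})

test_that("an open mesh is a geometry error", {
  mesh <- sphere_mesh()
  broken <- mesh
  broken$triangles <- mesh$triangles[-1, , drop = FALSE]
  expect_error(shape_descriptors(broken), "closed")
})

test_that("a stationary blob tracks with zero velocity", {
  mesh <- sphere_mesh()
  dirs <- memwave:::normalize_rows(mesh$nodes)
  blob <- exp(-(acos(pmin(1, dirs %*% c(1, 0, 0)))^2) / 0.5)
  sig <- signal_field(outer(as.numeric(blob), rep(1, 10)) +
                        matrix(rnorm(nrow(mesh$nodes) * 10, sd = 1e-4),
                               ncol = 10), dt = 10)
  tk <- track_domain(sig, mesh)
  expect_equal(nrow(tk), 10)
  vel <- decompose_velocity(tk, mesh)
  expect_lt(vel$v_mean, 0.2)
  # peak at the blob centre
  expect_lt(acos(sum(memwave:::normalize_rows(as.matrix(tk[1, c("x", "y", "z")])) *
                       c(1, 0, 0))), 0.1)
})

test_that("an all-flat signal yields an empty track", {
  mesh <- sphere_mesh()
  sig <- signal_field(matrix(1, nrow(mesh$nodes), 10), dt = 10)
  tk <- track_domain(sig, mesh)
  expect_equal(nrow(tk), 0)
})

test_that("domain speeds recover the circumference law within 5%", {
  for (T in c(120, 200, 300)) {
    for (bt in c(0, 0.4)) {
      spec <- scene_spec(radius = 3, omega = 0, pattern = "horizontal_wave",
                         period = T, noise_sd = 0.02, duration = 2 * T,
                         seed = 1, band_theta = bt)
      mesh <- sphere_mesh()
      gen <- make_signal(mesh, spec)
      vel <- decompose_velocity(track_domain(gen$signal, mesh), mesh)
      v_true <- 2 * pi * 3 * cos(bt) / T * 60
      expect_lt(abs(vel$v_mean - v_true) / v_true, 0.05)
    }
  }
})

test_that("velocity decomposition handles the degenerate directions", {
  mesh <- sphere_mesh()
  tt <- seq(0, 200, by = 10)
  # purely azimuthal rotation at fixed latitude: v_theta = 0, v_a flagged
  th0 <- 0.4
  az <- data.frame(frame = seq_along(tt), time = tt,
                   x = 3 * cos(th0) * cos(2 * pi * tt / 200),
                   y = 3 * cos(th0) * sin(2 * pi * tt / 200),
                   z = 3 * sin(th0), contrast = 1)
  v1 <- decompose_velocity(az, mesh)
  expect_lt(v1$v_theta, 1e-9)
  expect_false(v1$v_a_defined)
  expect_true(is.infinite(v1$v_a))
  # purely meridional rotation: v_a ~ 0; polar-crossing steps are dropped
  me <- data.frame(frame = seq_along(tt), time = tt,
                   x = 3 * cos(2 * pi * tt / 200 + 0.05),
                   y = 0,
                   z = 3 * sin(2 * pi * tt / 200 + 0.05), contrast = 1)
  v2 <- decompose_velocity(me, mesh)
  expect_lt(v2$v_a, 0.05)
  # components never exceed the step speed
  st <- rbind(v1$steps, v2$steps)
  expect_true(all(st$v + 1e-9 >= st$v_theta))
  expect_true(all(st$v + 1e-9 >= st$v_phi))
  expect_error(decompose_velocity(az[1:3, ], mesh), "5 tracked steps")
})

test_that("population fits recover an exactly linear composition", {
  da <- seq(-0.5, 0.5, length.out = 24)
  cells <- data.frame(delta_alpha = da, r_a = 0.1 + 0.2 * da,
                      v_a = 1 + 1.5 * da)
  pf <- population_fits(cells)
  expect_equal(pf$m, 1.5 / 0.2, tolerance = 1e-6)
  expect_equal(pf$n0, 1 - 1.5 * 0.1 / 0.2, tolerance = 1e-6)
  # guards
  expect_error(population_fits(cells[1:5, ]), "8 cells")
  one_bin <- data.frame(delta_alpha = rep(0.1, 10) + rnorm(10, sd = 1e-9),
                        r_a = runif(10), v_a = runif(10))
  expect_error(population_fits(one_bin), "fit error|spread")
  # infinite v_a rows are excluded, not propagated
  cells$v_a[3] <- Inf
  expect_equal(population_fits(cells)$m, 1.5 / 0.2, tolerance = 1e-6)
})

test_that("ensemble speed ratio of spherical cells is the isotropy intercept", {
  # at r_a = 0 the speed-ratio intercept is unity: pooled over random axes,
  # mean |v_phi| equals mean |v_theta|
  mesh <- sphere_mesh()
  set.seed(33)
  vth <- c(); vph <- c()
  for (k in 1:12) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    spec <- scene_spec(radius = 3, omega = 0, pattern = "horizontal_wave",
                       period = 200, noise_sd = 0.05, duration = 600,
                       seed = 40 + k, axis = ax)
    gen <- make_signal(mesh, spec)
    vel <- decompose_velocity(track_domain(gen$signal, mesh), mesh)
    vth <- c(vth, vel$steps$v_theta)
    vph <- c(vph, vel$steps$v_phi)
  }
  expect_lt(abs(mean(vph) / mean(vth) - 1), 0.25)
})
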