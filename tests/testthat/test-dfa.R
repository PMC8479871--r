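test_that("the cumulated sum is mean-free and telescopes to zero", {
  expect_equal(cumulate(rep(3, 6)), rep(0, 6))
  expect_equal(cumulate(c(1, -1, 1, -1)), c(1, 0, 1, 0))
  set.seed(2)
  x <- rnorm(100)
  S <- cumulate(x)
  expect_lt(abs(S[100]), 1e-10)
  expect_error(cumulate(c(1, 2)), "short")
})

test_that("the fluctuation function matches hand-computed least squares", {
  # perfect linear cumulated sum detrends to zero
  expect_equal(fluctuation_function(seq(0.5, 10, by = 0.5), tau = 5, order = 1),
               0, tolerance = 1e-12)
  # S = (0,1,0,1,0,1,0,1), tau = 4: per-segment fit 0.2*t, residual
  # SS = 0.8 per segment, F = sqrt(1.6 / 8)
  S <- rep(c(0, 1), 4)
  expect_equal(fluctuation_function(S, tau = 4, order = 1), sqrt(0.2),
               tolerance = 1e-12)
  # tau = N: single-segment residual
  set.seed(3)
  S2 <- cumsum(rnorm(20))
  fit <- lm(S2 ~ seq_along(S2))
  expect_equal(fluctuation_function(S2, tau = 20, order = 1),
               sqrt(mean(residuals(fit)^2)), tolerance = 1e-10)
  expect_error(fluctuation_function(S2, tau = 21), "exceeds")
  expect_error(fluctuation_function(S2, tau = 2, order = 1), "order")
})

test_that("DFA calibrations: white noise ~0.5, oscillation ~2, random walk ~1.5", {
  set.seed(10)
  a_noise <- mean(replicate(200, dfa_alpha(rnorm(200))$alpha))
  expect_lt(abs(a_noise - 0.5), 0.1)
  x <- cos(2 * pi * (0:179) * 10 / 300)
  a_osc <- dfa_alpha(x)$alpha
  expect_lt(abs(a_osc - 2), 0.2)
  set.seed(11)
  a_rw <- mean(replicate(200, dfa_alpha(cumsum(rnorm(200)))$alpha))
  expect_lt(abs(a_rw - 1.5), 0.1)
  # monotone discrimination with non-overlapping IQRs
  set.seed(12)
  noise <- replicate(200, dfa_alpha(rnorm(200))$alpha)
  walk <- replicate(200, dfa_alpha(cumsum(rnorm(200)))$alpha)
  osc <- replicate(200, {
    ph <- runif(1, 0, 2 * pi)
    dfa_alpha(cos(2 * pi * (0:199) * 10 / 300 + ph) +
                rnorm(200, sd = 1e-6))$alpha
  })
  expect_lt(quantile(walk, 0.25), quantile(osc, 0.25))
  expect_lt(quantile(noise, 0.75), quantile(walk, 0.25))
  expect_lt(quantile(walk, 0.75), quantile(osc, 0.25))
})

test_that("alpha is invariant to affine transforms of the series", {
  set.seed(4)
  x <- rnorm(120)
  a <- dfa_alpha(x)$alpha
  expect_equal(dfa_alpha(5 * x - 3)$alpha, a, tolerance = 1e-12)
  expect_equal(dfa_alpha(-0.1 * x + 100)$alpha, a, tolerance = 1e-10)
})

test_that("constant series have undefined alpha", {
  expect_error(dfa_alpha(rep(1, 100)), "undefined|vanishes")
})

test_that("the vectorised per-node map equals an independent naive DFA to 1e-10", {
  set.seed(20)
  n <- 50
  V <- matrix(rnorm(n * 120), n, 120)
  sig <- signal_field(V, dt = 10)
  am <- alpha_map(sig)
  ref <- vapply(seq_len(n), function(i) naive_dfa(V[i, ]), numeric(1))
  expect_lt(max(abs(am$alpha - ref)), 1e-10)
  # the scalar path agrees too
  ref1 <- dfa_alpha(V[1, ])$alpha
  expect_lt(abs(am$alpha[1] - ref1), 1e-12)
})

test_that("alpha maps classify oscillatory and noisy membrane regions", {
  mesh <- truncated_mesh()
  sig <- two_region_signal(mesh, ventral_oscillates = FALSE)
  am <- alpha_map(sig, mesh)
  above <- mesh$theta > mesh$theta_adh + 0.35
  below <- mesh$theta < mesh$theta_adh - 0.1
  frac <- mean(c(am$alpha[above] > 1, am$alpha[below] < 1))
  expect_gt(frac, 0.9)
})

test_that("white-noise alpha maps are unstructured around 0.5", {
  mesh <- truncated_mesh()
  spec <- scene_spec(radius = 3, omega = pi / 3, pattern = "white_noise",
                     noise_sd = 1, duration = 2000, seed = 6)
  gen <- make_signal(mesh, spec)
  am <- alpha_map(gen$signal, mesh)
  expect_lt(abs(mean(am$alpha) - 0.5), 0.1)
  # Moran's I over mesh adjacency ~ 0 (no spatial structure)
  e <- mesh_edges(mesh)
  a <- am$alpha - mean(am$alpha)
  moran <- (length(a) * sum(a[e[, 1]] * a[e[, 2]])) /
    (nrow(e) * sum(a^2))
  expect_lt(abs(moran), 0.1)
})

test_that("constant signals flag every node without aborting the map", {
  mesh <- sphere_mesh()
  sig <- signal_field(matrix(1, nrow(mesh$nodes), 100), dt = 10)
  am <- alpha_map(sig, mesh)
  expect_true(all(is.na(am$alpha)))
})

test_that("profile summaries separate oscillatory and noisy ventral membranes", {
  mesh <- truncated_mesh()
  pr_osc <- alpha_profile(alpha_map(two_region_signal(mesh, TRUE), mesh), mesh)
  expect_lt(pr_osc$delta_alpha, 0)
  pr_noise <- alpha_profile(alpha_map(two_region_signal(mesh, FALSE), mesh), mesh)
  expect_gt(pr_noise$delta_alpha, 0)
  expect_equal(pr_noise$delta_alpha,
               pr_noise$alpha_adh - pr_noise$alpha_min)
})

test_that("a spatially constant alpha map gives a flat profile with zero contrast", {
  mesh <- truncated_mesh()
  am <- list(alpha = rep(0.8, nrow(mesh$nodes)),
             r_squared = rep(1, nrow(mesh$nodes)))
  class(am) <- "alpha_map"
  pr <- alpha_profile(am, mesh)
  expect_equal(pr$delta_alpha, 0, tolerance = 1e-9)
  expect_equal(pr$alpha_min, 0.8, tolerance = 1e-9)
})

test_that("a cell without adhesion reports delta_alpha as not applicable", {
  mesh <- sphere_mesh()
  spec <- scene_spec(radius = 3, omega = 0, pattern = "white_noise",
                     noise_sd = 1, duration = 1000, seed = 7)
  gen <- make_signal(mesh, spec)
  pr <- alpha_profile(alpha_map(gen$signal, mesh), mesh)
  expect_true(is.na(pr$alpha_adh))
  expect_true(is.na(pr$delta_alpha))
})

test_that("the DFA configuration enforces its window invariants", {
  expect_error(dfa_config(dt = 10, tau_set = c(2, 5)), "order")
  expect_error(dfa_config(dt = 10, T_max = 100, tau_set = 4:18), "T_max")
  cfg <- dfa_config(dt = 10)
  expect_equal(cfg$tau_set, 4:18)
})
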