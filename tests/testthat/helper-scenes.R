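# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# default truncated cell (Omega = pi/3, R = 3 um) and its mesh
truncated_mesh <- function() {
  fixture("truncated_mesh", function() {
    make_geometry(scene_spec(radius = 3, omega = pi / 3))
  })
}

sphere_mesh <- function() {
  fixture("sphere_mesh", function() {
    make_geometry(scene_spec(radius = 3, omega = 0))
  })
}

# rendered stack + reconstruction round trip used by several modules
roundtrip_cell <- function() {
  fixture("roundtrip_cell", function() {
    spec <- scene_spec(radius = 3, omega = pi / 3, pattern = "horizontal_wave",
                       period = 200, noise_sd = 0.1, duration = 300, seed = 1)
    mesh <- make_geometry(spec)
    gen <- make_signal(mesh, spec)
    stack <- voxelize(mesh, gen$signal, stack_metadata(), psf_sd = 0.3)
    rec <- reconstruct_cell(stack)
    list(spec = spec, mesh = mesh, gen = gen, stack = stack, rec = rec)
  })
}

# pinned spiral analysed with an interior wavelet window (clear of the
# record boundary at the 2-min rotation period)
spiral_case <- function() {
  fixture("spiral_case", function() {
    spec <- scene_spec(radius = 3, omega = pi / 3, pattern = "pinned_spiral",
                       period = 120, noise_sd = 0.05, duration = 1500,
                       seed = 4)
    mesh <- make_geometry(spec)
    gen <- make_signal(mesh, spec)
    pm <- phase_map(gen$signal, mesh,
                    wavelet_config(t_min = 400, t_max = 1100))
    list(spec = spec, mesh = mesh, gen = gen, pm = pm)
  })
}

# two-region alpha scenes: oscillation confined to one side of the contact
# perimeter with a logistic taper (DFA profiles are smooth, so the taper is
# completed before the perimeter is reached)
two_region_signal <- function(mesh, ventral_oscillates, period = 240,
                              noise_sd = 0.08, seed = 5) {
  spec <- scene_spec(radius = 3, omega = pi / 3, pattern = "quiet",
                     noise_sd = noise_sd, duration = 1800, seed = seed)
  gen <- make_signal(mesh, spec)
  sig <- gen$signal
  tt <- signal_times(sig)
  osc <- cos(2 * pi * tt / period)
  shift <- if (ventral_oscillates) -0.35 else 0.35
  w <- 1 / (1 + exp(-(mesh$theta - (mesh$theta_adh + shift)) / 0.15))
  if (ventral_oscillates) w <- 1 - w
  sig$values <- sig$values + outer(w, osc)
  sig
}

# independent brute-force DFA1 (no code shared with the package paths)
naive_dfa <- function(x, taus = 4:18, order = 1) {
  S <- cumsum(x - mean(x))
  Fv <- vapply(taus, function(tau) {
    nseg <- length(S) %/% tau
    ss <- 0
    for (s in seq_len(nseg)) {
      idx <- ((s - 1) * tau + 1):(s * tau)
      fit <- stats::lm(S[idx] ~ stats::poly(seq_len(tau), order, raw = TRUE))
      ss <- ss + sum(stats::residuals(fit)^2)
    }
    sqrt(ss / (nseg * tau))
  }, numeric(1))
  unname(stats::coef(stats::lm(log(Fv) ~ log(taus)))[2])
}

# bisection root of 2g + sin(2g) = pi*sin(lat), independent of solve_gamma;
# at the exact poles the root is analytic (2*(pi/2) + sin(pi) = pi) and a
# double root, where bisection loses accuracy to floating point
bisect_gamma <- function(lat, tol = 1e-12) {
  if (abs(abs(lat) - pi / 2) < 1e-15) return(sign(lat) * pi / 2)
  f <- function(g) 2 * g + sin(2 * g) - pi * sin(lat)
  lo <- -pi / 2
  hi <- pi / 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
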