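# memwave

Entire-membrane analysis of excitable signaling waves on adherent cells.

Signaling lipids such as PIP3 form self-organised travelling domains on the
plasma membrane of amoeboid cells. On actin-inhibited, substrate-adhered
cells — well approximated by a sphere of radius *R* truncated by the
coverslip — these dynamics can be measured over the *entire* membrane, and
the ring of maximal curvature where the flat ventral membrane meets the free
membrane (the **contact perimeter**, at polar angle θ_adh = −π/2 + Ω for
contact angle Ω) turns out to organise them: it can block, guide, and pin
waves. `memwave` provides the complete measurement chain for this setting:

- **3D reconstruction** — membrane localisation in 4D fluorescence stacks by
  the temporal-fluctuation maximum along rays, closed Delaunay surface
  meshing at ≈0.3 µm² mean node area, contact-perimeter detection, and
  per-node signal extraction (`locate_membrane()`, `triangulate_surface()`,
  `detect_contact_perimeter()`, `sample_signal()`).
- **Equal-area maps and kymographs** — Mollweide projection
  (x = (2√2/π)·φ·cos γ, y = √2·sin γ, with 2γ + sin 2γ = π·sin θ solved by
  Newton–Raphson) and azimuth–time kymographs of latitude bands
  (`mollweide_project()`, `render_map()`, `extract_kymograph()`).
- **Fluctuation analysis** — per-node first-order DFA over windows up to
  T_max = 180 s: F(τ) ~ τ^α with α ≈ 0.5 for white noise and α → 2 for a
  noise-free oscillation; α maps, θ-profiles and the ventral contrast
  Δα = α_adh − α_min (`dfa_alpha()`, `alpha_map()`, `alpha_profile()`).
- **Phase analysis** — complex Morlet transform
  ψ(t) = ω^(−1/2)·e^{iωt}·e^{−t²/2} with ω = 2π, ridge extraction of the
  dominant period, wave-front phase convention (peak ≡ 2π),
  phase-singularity detection by discrete winding numbers, tracking and
  pinning classification at the contact perimeter (`phase_map()`,
  `find_singularities()`, `track_singularities()`).
- **Kinematics** — shape descriptors (V, A_adh, A_mem, r_a = A_adh/A_mem,
  Ω from r_a = sin²Ω/(4 − (1 − cos Ω)), κ_max), spherical-harmonic domain
  tracking, velocity decomposition (v, v_θ, v_φ, v_a = ⟨v_φ⟩/⟨v_θ⟩) and
  population fits v_a = m·r_a + n₀ (`shape_descriptors()`,
  `track_domain()`, `decompose_velocity()`, `population_fits()`).
- **Synthetic cells** — a ground-truth generator for truncated-sphere
  geometries, rotating waves, transient spots, pinned spirals and noise,
  plus a confocal-like voxel renderer, so the whole pipeline is testable
  without any recording (`scene_spec()`, `make_geometry()`,
  `make_signal()`, `voxelize()`); `run_pipeline()` orchestrates all stages
  from one seeded configuration.

## Worked example

A synthetic cell (R = 3 µm, Ω = 60°) carrying a spiral wave pinned at the
contact perimeter, analysed end to end:

```r
library(memwave)

spec <- scene_spec(radius = 3, omega = pi/3, pattern = "pinned_spiral",
                   period = 120, noise_sd = 0.05, duration = 1500, seed = 4)
mesh <- make_geometry(spec)
gen  <- make_signal(mesh, spec)

shape_descriptors(mesh)
#> cell_geometry: V = 0.094 pL, A_mem = 105.2 um^2, A_adh = 21.0 um^2
#>   r_a = 0.200, Omega = 57.3 deg, R = 3.00 um, kappa_max = 1.55 1/um

alpha_profile(alpha_map(gen$signal, mesh), mesh)
#> alpha_profile: alpha_min = 1.379, alpha_adh = 1.334, delta_alpha = -0.045

pm <- phase_map(gen$signal, mesh, wavelet_config(t_min = 400, t_max = 1100))
sings  <- lapply(seq_along(pm$time), function(t) find_singularities(pm, mesh, t))
tracks <- track_singularities(sings, mesh)
tracks[, c("track_id", "lifetime", "charge", "mean_dist_perimeter", "pinned")]
#>   track_id lifetime charge mean_dist_perimeter pinned
#> 1        1       71      1           3.0556136  FALSE
#> 2        2       71     -1           0.4222318   TRUE
```

Reading the output: the recovered contact angle (57.3°, from inverting the
area-ratio model on the measured r_a = 0.200) sits within the model's known
offset of the true 60°; the mildly negative Δα reflects the spiral's
oscillatory activity reaching the ventral membrane; and of the two phase
singularities required by closed-surface topology, the one 0.42 µm from the
contact perimeter is classified *pinned* while its counter-rotating partner
high on the cell body is *free* — the signature of a perimeter-pinned
spiral.

`render_map(mesh, gen$signal$values[, 10])` produces the corresponding
equal-area membrane map (plot with `plot()`), and
`extract_kymograph(gen$signal, mesh, "center")` the azimuth–time kymograph
of the equatorial band.

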