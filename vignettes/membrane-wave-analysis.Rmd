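---
title: "Entire-membrane analysis of excitable signaling waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entire-membrane analysis of excitable signaling waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memwave)
```

## The system and the analysis problem

Actin-polymerisation-inhibited *Dictyostelium* cells are nearly immobile,
nearly spherical cells adhered to a flat substrate. Their shape is well
described by a sphere of radius $R$ truncated by the coverslip: the adhered
(ventral) membrane is a flat disc, and the ring where it meets the free
membrane — the **contact perimeter** at polar angle
$\theta_{adh} = -\pi/2 + \Omega$, with $\Omega$ the contact angle — is the
region of highest membrane curvature. Signaling lipids such as PIP3 form
self-organised domains on the membrane: rotating waves parallel to the
contact perimeter, waves crossing it, transient spots, and spiral waves
whose rotation cores can sit ("pin") on the perimeter.

`memwave` implements the full analysis chain for such recordings:

1. **Reconstruction** of the membrane as a closed triangulated surface from
   a 4D fluorescence stack, with per-node signal time series.
2. **Equal-area mapping** (Mollweide projection) of per-node fields and
   azimuth–time kymographs of latitude bands.
3. **Spatially resolved detrended fluctuation analysis** (DFA): a
   per-node scaling exponent $\alpha$ separating noise-dominated
   ($\alpha < 1$) from signal-dominated ($\alpha > 1$) membrane regions,
   summarised by the ventral contrast
   $\Delta\alpha = \alpha_{adh} - \alpha_{min}$.
4. **Wavelet phase analysis**: per-node instantaneous phase and dominant
   period from a complex Morlet transform, phase-singularity detection by
   discrete winding numbers, singularity tracking, and pinning/guidance
   classification at the contact perimeter.
5. **Kinematics**: shape descriptors ($V$, $A_{adh}$, $A_{mem}$,
   $r_a = A_{adh}/A_{mem}$, $\Omega$, $\kappa_{max}$), domain-peak tracking
   through a spherical-harmonic projection, velocity decomposition into
   polar/azimuthal components, and population-level linear relations.

Because recordings of this kind are not generally available, the package
carries a first-class synthetic-cell generator (`scene_spec()`,
`make_geometry()`, `make_signal()`, `voxelize()`) that produces every input
with known ground truth; the whole pipeline is tested against it.

## Geometry and coordinates

`make_geometry()` builds the truncated sphere: a Fibonacci lattice on the
spherical part, a rim ring and a sunflower layout on the ventral disc, and
a spherical Delaunay triangulation of the node directions (planar Delaunay
of the stereographically projected directions, closed by a fan around the
projection pole; closure and Euler characteristic 2 are asserted on every
mesh). Node density targets a mean node area of 0.3 µm², matching the
resolution of the reconstruction stage.

Surface coordinates are the polar angle $\theta \in [-\pi/2, \pi/2]$
(with $-\pi/2$ at the ventral centre) and the periodic azimuth
$\phi \in [-\pi, \pi]$. The ventral disc is parameterised in $\theta$
linearly in radial position from $-\pi/2$ (centre) to $\theta_{adh}$ (rim),
so 2D maps cover the whole closed surface. This disc parameterisation is a
convention of this package: maps of the ventral membrane depend on it, but
no quantitative statistic does (disc node areas, adhesion areas and
singularity positions are all computed in 3D).

At $\Omega = \pi/2$ the disc passes through the sphere centre, so the
star-shape viewpoint used for triangulating directions is placed midway
between the disc plane and the top of the cell; the mesh orientation is
inherited from that triangulation.

## The area-ratio model

The adhesion area ratio is modelled as

$$ r_a = \frac{\sin^2\Omega}{4 - (1 - \cos\Omega)} , $$

which rises from 0 at $\Omega = 0$ to $1/3$ at $\Omega = \pi/2$ and is
inverted numerically (bisection to $10^{-10}$) by `contact_angle()`; the
analytic inverse — the root of $c^2 + r_a c + 3 r_a - 1 = 0$ in
$c = \cos\Omega$ — is provided as `contact_angle_closed_form()` and agrees
with the bisection to $10^{-7}$ over the whole branch. The *exact*
truncated-sphere ratio (disc over free-cap-plus-disc,
`area_ratio_exact()`) agrees with the model at both endpoints but deviates
by up to 7.2% near $\Omega \approx 62°$. The model form is canonical
throughout the package and the discrepancy is asserted, not hidden, in the
test suite; its practical consequence is a systematic offset of about
$-2.8°$ when a contact angle of 60° is recovered from a measured area
ratio, which is why the reconstruction round trip is validated against a
$\pm 5°$ contract rather than a tighter one.

## Reconstruction choices

- **Membrane localisation** uses the per-voxel temporal standard deviation:
  the membrane carries temporal signal variation, the cytosol does not.
  Radial profiles along 500 quasi-uniform rays from the intensity centroid
  are interpolated trilinearly; the argmax is refined by a quadratic fit
  over a window matched to the coarsest voxel scale and centred on the
  interpolated plateau (a blurred peak falling between z-planes produces an
  exactly flat top under trilinear interpolation, where a three-point fit
  is degenerate). Rays without an interior maximum are filled from
  neighbouring directions; more than 20% such rays is a failure.
- **Resampling**: the raw cloud is triangulated, its area estimated, and
  the surface re-sampled on a Fibonacci direction set sized to a mean node
  area of 0.3 µm², with radii interpolated by inverse-distance weighting in
  direction space; one pass of Gaussian one-ring smoothing
  (`smooth_nodes()`, width half the mean edge length) relaxes
  voxel-quantisation jitter. Wider kernels shrink the surface measurably
  (Laplacian-type behaviour, shown in the tests), which is why a single
  conservative pass is the default.
- **Contact detection** (`detect_contact_perimeter()`): nodes within
  `flatness_tol` (default 0.5 µm, the typical axial voxel size) of the
  ventral plane are adherent. The plane is the median height of the lowest
  candidate band rather than the single lowest node, and a flat-disc test —
  patch area at least 1.4× the spherical-cap area of equal height —
  prevents a bare sphere bottom from being misread as adhesion. With
  axial sampling of 0.5 µm, adhered patches of small contact angle
  ($\Omega \lesssim 25°$) are not reliably separable from a spherical cap;
  this is a resolution limit of the data, not of the implementation.
- **Effective radius**: an algebraic least-squares sphere fit through the
  free nodes clear of the rim. The intensity centroid used for ray casting
  sits above the sphere centre of a truncated cell, so radial medians about
  it would be biased.

The simulate → voxelize → reconstruct round trip recovers $R$ within 5%,
$r_a$ within 15% relative, per-node signal correlation above 0.9, and
$\Omega = 60°$ within $\pm 5°$ (including the model offset above); all of
these are asserted in the test suite at exactly these numbers.

## DFA

For each node series $s(t_i)$ the mean-free cumulative sum
$S_i = \sum_{k \le i} (s_k - \bar s)$ is split into non-overlapping windows
of $\tau$ samples taken from the start (the shorter tail is discarded); a
least-squares line (order 1 by default) is removed per window and
$F(\tau)$ is the root mean squared residual. The exponent $\alpha$ is the
unweighted least-squares slope of $\log F$ against $\log \tau$ over all
integer windows from 4 samples to $\lfloor T_{max}/dt \rfloor = 18$ samples
($T_{max} = 180$ s at $dt = 10$ s). With only 15 window lengths available,
decimating the grid or weighting the fit would destabilise the slope, so
neither is done. The per-node map (`alpha_map()`) is a vectorised
implementation sharing the per-window projection matrix across nodes; it is
tested to $10^{-10}$ against a naive independent implementation.

Reference behaviours recomputed in the tests and the acceptance script:
i.i.d. Gaussian noise gives ensemble-mean $\alpha \approx 0.57$ at these
short window lengths (the classic small-scale bias of DFA1 above the
asymptotic 0.5, well inside the 0.5 ± 0.1 calibration band); a random walk
gives $\approx 1.5$; a noise-free oscillation probed well below its period
approaches 2. At finite record length the oscillation value depends on the
record's phase: the package convention for reference oscillations is
peak-aligned at $t = 0$ (cosine), the same convention that places the wave
front at phase $2\pi$ in the phase module.

The $\theta$-profile (`alpha_profile()`) bins node exponents by $\theta$
(node-area weights), fits a polynomial of order 4 (the smallest order that
accommodates the single-inflection profiles seen in practice; configurable)
to the bin medians weighted by bin occupancy, and evaluates it at
$\theta_{min} = -\pi/2$ and $\theta_{adh}$ to give $\alpha_{min}$,
$\alpha_{adh}$ and $\Delta\alpha = \alpha_{adh} - \alpha_{min}$. A negative
$\Delta\alpha$ indicates an oscillatory ventral membrane, a positive one a
noise-dominated ventral membrane. A global polynomial cannot follow a
discontinuous step in $\alpha$ without edge ringing; the synthetic
two-region scenes used in the tests therefore taper the oscillation
amplitude smoothly (logistic in $\theta$, width 0.15 rad, completed before
the perimeter is reached), which is also the physically expected shape of a
diffusively coupled boundary.

## Phase analysis

The complex Morlet wavelet
$\psi(t) = \omega^{-1/2} e^{i\omega t} e^{-t^2/2}$ with $\omega = 2\pi$ is
applied per node over 40 log-spaced periods spanning 60–600 s; at
$\omega = 2\pi$ the dilation equals the probed period. The printed
$\omega^{-1/2}$ normalisation is kept as stated; only amplitude *ratios*
(ridge selection, the amplitude guard) enter any decision, so the absolute
normalisation is immaterial. Series are mean-subtracted before the
transform because kernels truncated at the record boundaries are not
exactly zero-mean, and a baseline would otherwise leak into the largest
scales. Per time point the scale of maximal amplitude is the ridge;
amplitude ties resolve to the lower frequency. Phase is stored in
$(0, 2\pi]$ with the intensity peak at $2\pi$ — the wave-front convention —
and is never unwrapped in time nor smoothed in space.

Phase singularities are faces whose oriented vertex loop winds by
$\pm 2\pi$ (each difference wrapped to $(-\pi, \pi]$). On a closed surface
the winding numbers cancel identically, which the tests assert per frame.
Two guards apply: a face in a quiescent region (a majority of its nodes
below 10% of the cell-median ridge amplitude) is skipped — a *single*
low-amplitude node never disqualifies a face, because the core of a genuine
spiral is itself an amplitude zero — and frames inside the cone of
influence of the record start at the cell's dominant scale are skipped
entirely, because boundary-biased phase mislocates spiral cores by of order
1 µm. For the same reason, analyses that quantify pinning should use an
analysis window clear of the record boundary: with $\omega = 2\pi$ the
Gaussian envelope of the wavelet has a standard deviation of one full
period, so a window starting at 60 s is strongly boundary-affected for
2-minute oscillations. The default window (60–330 s) is retained for
compatibility with short recordings; the pinning tests use a 1500-s
synthetic record with a 400–1100 s window.

Tracking (`track_singularities()`) is greedy nearest-neighbour linking with
a distance gate of twice the pinning distance per frame and matching
charges; gaps terminate tracks, and tracks shorter than 3 frames are
discarded as flicker. Track positions are smoothed by a 5-frame rolling
median before distances to the contact-perimeter ring are computed — the
winding detector localises only to face resolution, and pinning is a
temporal notion. A track is *pinned* when at least 80% of its lifetime lies
within 1 µm of the perimeter ring (both parameters exposed). Wave-front
guidance along the perimeter (`detect_guidance()`) is flagged when the
principal axis of the near-perimeter front nodes aligns with the local
azimuthal direction within 20° for at least 3 consecutive frames.

## Kinematics and populations

Domain peaks are found per frame after projecting the node signal onto real
spherical harmonics up to degree 3 (the octupole moment) by least squares
on the scattered node directions — quadrature is not meaningful on an
irregular mesh, and degree 3 keeps the 16-column system strongly
overdetermined even on the smallest (about 620-node) meshes. The peak
position is refined below node resolution by an intensity-weighted centroid
of the upper part of the reconstructed profile; frames with less than 20%
of the best frame's reconstructed contrast are skipped. Steps between
consecutive peaks use the Euclidean chord (at 10-s sampling the
chord–geodesic difference is below 1% for the speeds involved), decomposed
along local polar and azimuthal unit tangents at the step midpoint, with
absolute values averaged per cell; the speed anisotropy is
$v_a = \langle v_\phi \rangle / \langle v_\theta \rangle$.

For a perfect sphere with isotropically oriented rotating domains the
expected speed ratio is unity. The *mean over per-cell ratios* is, however,
strongly right-skewed: a rotation axis near the vertical makes
$v_\theta \to 0$ and the per-cell ratio diverge, so the mean of ratios
exceeds 1 by Jensen's inequality even under perfect isotropy. The isotropy
statistic used in the acceptance suite is therefore the **ensemble speed
ratio** — pooled mean $|v_\phi|$ over pooled mean $|v_\theta|$ across all
steps of all cells — which is the quantity the isotropy argument actually
constrains, and which equals 1 within a few percent in the simulations.
Per-cell ratios are retained unchanged for population fits, which use
binned medians exactly because of this skew.

`population_fits()` bins a per-cell table by $\Delta\alpha$, takes per-bin
medians, fits $r_a$ and $v_a$ linearly against the median $\Delta\alpha$
(occupancy-weighted), and eliminates $\Delta\alpha$ to obtain
$v_a = m\, r_a + n_0$. The bin-median abscissa makes the composition exact
for exactly linear populations (tested to $10^{-6}$). Cells with undefined
(infinite) $v_a$ are excluded. The intercept $n_0$ at $r_a = 0$ is the
isotropy baseline above.

## What the generator emulates — and what it does not

The generator reproduces: truncated-sphere geometry over the full
$\Omega \in [0, \pi/2]$ range; mesh resolution matched to the
reconstruction contract; rotating wave domains (any axis, any band
latitude, Gaussian angular profile, period default 200 s in the observed
2–5 min band); transient spots (Poisson births, exponential-shoulder
profile, positions above the perimeter); prescribed pinned spirals with the
topologically required counter-singularity at the antipode; additive white
Gaussian noise (the regime in which the DFA baselines $\alpha = 0.5/2$ are
stated) seeded per node, so fields are bit-reproducible and node series do
not depend on mesh size; and a confocal-like renderer (trilinear splatting
weighted by node area, dimmer uniform cytosol, isotropic Gaussian PSF,
0.2666 × 0.2666 × 0.5 µm voxels at 10-s frames).

It does not emulate: photobleaching or shot noise, membrane deformation
(cells are treated as rigid, as for actin-inhibited cells), irregular
ventral footprints, reaction–diffusion mechanisms (waves are kinematic
prescriptions, so synthetic populations carry no built-in $v_a$–$r_a$
coupling), or camera-specific noise. Passing tests therefore demonstrate
correctness of the measurement chain on known inputs — not that real
membranes satisfy any particular model.

## Problem sizes and determinism

The test-suite simulations use cells of radius 2–3 µm (roughly 340–380
nodes at 0.3 µm²/node), records of 300–2000 s at 10-s sampling, ensembles
of 200 series for DFA calibrations and 50 random axes for the isotropy
baseline; the acceptance script uses 500 noise series of 200 samples and an
800-point sphere cloud. Every stochastic draw is keyed to an explicit seed;
reruns are bit-identical, which the pipeline test asserts on the written
CSV artifacts.

## Known limitations

- The $\Omega$ estimate inherits the model/exact area-ratio discrepancy
  (up to $\approx 2.8°$ near 60°) by design, since the model form is
  canonical.
- Small contact angles ($\lesssim 25°$) are below the adhesion-detection
  resolution at 0.5-µm axial sampling.
- Discrete mean curvature on irregular meshes is noisy at single nodes;
  `kappa_max` is a perimeter-ring maximum of a cotangent-Laplacian
  estimate and should be read as a descriptor, not a precision measurement
  (the contact angle is the robust curvature proxy).
- Phase near the record boundaries is boundary-biased at long periods;
  use interior analysis windows for singularity statistics.
- The guidance detector is a geometric heuristic (front-axis alignment);
  it flags candidate episodes rather than proving guidance.
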