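Package: memwave
Title: Entire-Membrane Analysis of Excitable Signaling Waves on Cell Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct the plasma membrane of adherent,
    actin-inhibited cells from 4D fluorescence stacks as a triangulated
    surface, and to analyse signaling-wave dynamics on the entire membrane:
    equal-area (Mollweide) surface maps and kymographs, spatially resolved
    detrended fluctuation analysis (DFA exponent maps and the ventral versus
    contact-perimeter contrast), Morlet-wavelet phase maps with
    phase-singularity detection, tracking and pinning classification at the
    contact perimeter, and cell-shape and wave-kinematics descriptors
    (contact angle, adhesion area ratio, domain speeds and their anisotropy).
    A synthetic-cell generator produces truncated-sphere geometries,
    prototypical wave patterns and rendered voxel stacks with known ground
    truth, so every stage of the pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    interp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
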