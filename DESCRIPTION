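Package: tidesr
Title: Time-Varying Signaling Edge Strength Along Single-Cell Pseudotime Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Quantifies how the statistical dependency between pairs of
    proteins measured by mass cytometry changes along a pseudotime
    trajectory. Provides fast heat-diffusion kernel density estimation in
    one to three dimensions via the discrete cosine transform, conditional
    density rescaled visualization (DREVI) surfaces, conditional density
    resampled mutual information (DREMI) scores in two and three
    dimensions, Trajectory Interpolated DREMI Scores (TIDES) that track
    edge strength continuously along pseudotime, driver-edge ranking,
    perturbation impact-curve validation, phenotype gating, and seeded
    synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
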