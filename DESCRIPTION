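Package: csutools
Title: Conformational Ensembles and Anisotropic Map Analysis for
    Chemoreceptor Core Signaling Units
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale tools for studying domain flexibility in the
    bacterial chemotaxis core signaling unit: rigid-body sampling of a
    mobile kinase domain about a short backbone hinge with simulated
    annealing and a clash-based energy, loop-closure filtering of the
    resulting ensembles, QCP minimum-RMSD superposition, principal
    component analysis and centroid-linkage (UPGMC) clustering with
    medoid selection, salt-bridge persistence statistics on
    trajectories, model-derived density map simulation and local
    cross-correlation scoring, conical Fourier shell correlation for
    anisotropic resolution estimation, and matched anisotropic low-pass
    filtering.  Includes synthetic-data generators with planted,
    recoverable ground truth so the whole pipeline is testable without
    external inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
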