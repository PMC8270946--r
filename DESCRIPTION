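Package: imanifold
Title: Intrinsic Manifolds of Brain-State Dynamics from fMRI Phase Coherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the low-dimensional intrinsic manifold underlying
    parcellated BOLD fMRI dynamics and decodes brain states (wakefulness and
    NREM sleep stages) on it. The pipeline band-pass filters regional time
    series into the ultraslow band, extracts instantaneous phases via the
    analytic signal, builds per-timepoint phase-coherence states and their
    coherence connectivity dynamics (CCD) matrix, prunes the state-similarity
    structure with a relaxed minimum spanning tree, embeds timepoints with
    Laplacian eigenmaps (with a PCA baseline), aligns per-subject manifolds by
    landmark Procrustes analysis, and classifies stages with linear support
    vector machines under cross-validation, phase-randomized surrogate
    significance testing and ROC analysis. A Kuramoto-oscillator synthetic
    generator with planted stage-dependent coupling makes every stage of the
    pipeline testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    vegan,
    pROC,
    optparse
Config/testthat/edition: 3
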