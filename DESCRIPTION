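Package: confens
Title: Automated Refinement of Molecular Conformer Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for refining externally generated molecular conformer
    ensembles: multi-structure XYZ input/output, quasi-rigid-rotor
    harmonic-oscillator (qRRHO) thermochemistry with damped low-frequency
    entropies, Boltzmann population weighting, duplicate removal by joint
    energy and rotational-constant filtering, energy-window pruning,
    PCA-guided K-means clustering with silhouette-driven cluster-count
    selection, Boltzmann-weighted IR/VCD/UV/ECD spectral convolution, and
    bounded optimisation of spectral shift and line width against
    experimental spectra. Refinement protocols are described as JSON files
    and executed step by step against a pluggable calculator interface; a
    deterministic synthetic calculator is included so complete workflows run
    without any quantum-chemistry engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
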