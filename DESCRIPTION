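Package: pctomo
Title: Propagation-Based Phase-Contrast Tomography Simulation and Vessel Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates synchrotron inline (propagation-based) phase-contrast
    projection imaging of air-filled vascular phantoms, performs flat-/dark-field
    correction, fringe-visibility distance optimization, single-distance Paganin
    phase retrieval, and parallel-beam filtered back projection, then segments the
    vasculature by multiscale Hessian ridge detection with asymmetric-Gaussian
    ridge descriptors and quantifies branching morphometry: per-junction pre- and
    post-branching radii and their ratio K, radius filtering and binning, and
    group comparison by Student's t-test. Intended for contrast-agent-free
    micro-vascular imaging studies where air-tissue interfaces provide the
    imaging contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    mclust,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
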