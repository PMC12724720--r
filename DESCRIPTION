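Package: ringbump
Title: Head-Direction Bump Analytics and Plastic Ring-Attractor Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Circular population-vector analytics for ellipsoid-body calcium
    imaging of the Drosophila head-direction system, together with the
    machinery needed to exercise them end to end on synthetic data: seeded
    generators for walking behavior, wedge-ROI fluorescence sessions,
    optogenetic pairing protocols, neuron skeletons and neuropil meshes;
    the imaging preprocessing chain (motion correction, wedge extraction,
    log-domain detrending, z-scoring and smoothing, behavior alignment);
    population vector averages, bump-cue offsets, remapping error, lag and
    binned analyses; a 32-unit ring-attractor head-direction network with
    presynaptically- or postsynaptically-gated inhibitory visual plasticity;
    and connectome geometry (ring coordinate frames from mesh PCA, peeled
    convex hulls, cable distance between synapse classes on skeleton graphs).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
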