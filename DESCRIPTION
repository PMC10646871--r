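Package: EulerProfiles
Title: Euler Characteristic Curves and Profiles for Pointclouds and Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Distributed computation of Euler characteristic curves (ECCs)
    and n-parameter Euler characteristic profiles (ECPs) as stable
    topological summaries of data. Contribution lists are computed for
    Vietoris-Rips flag complexes built from pointclouds and, in a streaming
    fashion, for cubical complexes built from single- or multi-channel
    images of arbitrary dimension (T-construction). The package also
    provides multicritical contribution handling for general multiparameter
    filtrations, L1 distances between curves and between truncated
    profiles, fixed-length vectorizations for machine-learning pipelines,
    Betti curves and a brute-force 1-Wasserstein matcher for empirical
    verification of the stability bounds, independent brute-force oracles,
    and synthetic data generators (noisy spheres, RGB textures, random
    persistence diagrams).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
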