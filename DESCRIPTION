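Package: cxdisim
Title: Simulation of Coherent X-Ray Diffractive Imaging Experiments at XFEL Sources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulator for coherent X-ray diffractive imaging (CXDI) of
    noncrystalline biological particles at X-ray free-electron laser sources.
    Generates single-particle imaging (SPI), particle-aggregate, fluctuation
    X-ray scattering (FXS) and Fourier-transform holography (FTH) diffraction
    datasets from atomic or coarse-grained particle models. Diffraction is
    computed by direct summation of atomic form factors into a precomputed 3D
    reciprocal-space volume, with per-shot Ewald-sphere slicing by trilinear
    interpolation. Includes a configurable stack of realistic noise sources
    (Poisson photon counting, SASE spectra, fluence jitter, beam miscentering,
    fluctuating dark noise, static background, auto-ranging detector gain),
    conformational heterogeneity via anisotropic-network-model normal modes,
    continuum hydration shells, ballistic hit-and-stick aggregation, and
    validation utilities (radial profiles, Fourier shell correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    bio3d,
    rhdf5,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
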