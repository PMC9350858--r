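Package: photonsdf
Title: Meshless Monte Carlo Photon Transport in Signed-Distance-Function Geometry
Version: 0.1.0
Authors@R:
    person("photonsdf", "developers", email = "photonsdf@example.org",
           role = c("aut", "cre"))
Description: A Monte Carlo radiation transfer (MCRT) simulator for light
    transport in turbid media in which all geometry is represented by signed
    distance functions (SDFs). Photon packets are advanced by sphere tracing,
    so smooth curved surfaces (spheres, capsules, cylinders and their
    constructive-solid-geometry combinations) are represented exactly rather
    than voxelised or meshed, and refractive-index boundaries are resolved on
    the implicit surface with Fresnel reflection and Snell refraction. Fluence
    is recorded on a voxel grid with an exact path-length estimator. Includes
    packaged validation scenarios (isotropic-sphere scattering statistics,
    semi-infinite slab fluence with a two-exponential depth fit, a refractive
    glass sphere, a glass bottle annulus and capsule-network vessel models),
    a JSON scene-configuration reader and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
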