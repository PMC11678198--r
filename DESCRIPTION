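Package: lumisphere
Title: Optical Properties of Photoluminescent Turbid Slabs from
    Single-Integrating-Sphere Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines the absorption coefficient and the reduced scattering
    coefficient of photoluminescent turbid slabs from single-integrating-sphere
    reflectance and transmittance measurements. Provides a photon-packet Monte
    Carlo solver of the radiative transfer equation for plane-parallel slabs,
    Mie-theory computation of the scattering asymmetry factor for particle-loaded
    matrices, an analytic single-sphere radiation-exchange correction, a
    Monte Carlo lookup-table forward model with two-dimensional inversion,
    excitation-resolved spectral processing that separates elastic scattering
    from photoluminescence, and a synthetic measurement generator that emulates
    dye-and-scatterer phantoms for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
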