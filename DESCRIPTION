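Package: cobrachy
Title: Monte Carlo TG-43 Dosimetry of an HDR Cobalt-60 Brachytherapy Source
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analog Monte Carlo photon transport through a nested-cylinder
    model of a high-dose-rate cobalt-60 brachytherapy source (BEBIG model
    Co0.A86), with linear track-length collision-kerma scoring in air and
    water phantoms and extraction of the AAPM TG-43U1 dosimetry
    parameters: air kerma strength, dose rate constant, radial dose
    function and anisotropy function. Ships embedded photon interaction
    coefficient tables for the four source media, a compiled transport
    core, batch-based type-A uncertainty estimation, and closed-form
    testing modes (vacuum, primary-only, bare point source).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
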