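Package: nirdosim
Title: Voxel Monte Carlo Dosimetry for Near-Infrared Light Therapy of the Head
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds multispectral voxel optical phantoms of the human head from
    tissue probability maps, simulates near-infrared photon transport with a
    voxel Monte Carlo engine (Henyey-Greenstein scattering, Fresnel refraction,
    Russian roulette, time-resolved fluence recording), and analyses the
    results for photobiomodulation treatment planning: effective-attenuation
    and fluence depth profiles, region-of-interest energy deposition tables,
    energy-flow (Sankey) accounting, temporal point spread functions,
    region-response correlation and UPGMA clustering, dose-response
    regression, and ANSI Z136.1 maximum-permissible-exposure safety checks.
    Synthetic layered-head and slab phantom generators make every analysis
    runnable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    car,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
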