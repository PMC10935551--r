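Package: hgtrace
Title: Mercury Food-Web Bioaccumulation and Seafood Exposure Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-balanced trophic food-web modelling with contaminant tracking
    for assessing mercury release into shelf seas such as the North Sea. Builds
    Ecopath-style static mass balances, integrates an Ecotracer-style linear
    contaminant dynamic over the food web, constructs pipeline-decommissioning
    release scenarios, validates modelled muscle-tissue concentrations against
    observations (model/observed ratio, normalized mean bias), and derives
    human dietary exposure metrics (estimated weekly intake of methylmercury,
    tolerable-weekly-intake and food-standard exceedance, hazard quotient).
    Includes a synthetic generator for mass-balanced food webs, observation
    sets and consumer profiles so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
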