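Package: mpsink
Title: Water-Column Model of the Biological Microplastic Sink
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-compartment Eulerian microplastic model (free,
    marine-snow-aggregated, and faecal-pellet-bound particles) coupled to a
    minimal nutrient-phytoplankton-zooplankton-detritus ecosystem in a
    vertical ocean water column. Provides the plastic-waste emission forcing,
    prescribed temperature scenarios, flux-form vertical transport with a
    buoyant-rise sub-population and a seafloor return fraction, export
    efficiency and depth-bracket diagnostics, and Latin-hypercube parameter
    ensembles with plausibility filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
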