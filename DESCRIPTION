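Package: lgraf
Title: Process-Based Generation of Smallholder-Dominated Agricultural Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Generates gridded land-use mosaics of agricultural landscapes
    shaped by smallholder farming households. Roads are imported from vector
    data or created procedurally; households settle in villages along the
    road network and establish fields of sampled sizes in their vicinity
    using switchable search strategies; crop types are distributed over
    fields by landscape-level fractions or with household-level
    specialization. The package also computes the class-level landscape
    metrics (landscape shape index, largest patch index, mean patch area,
    number of patches, patch cohesion index) commonly used to characterize
    such maps, and exports all map products as ESRI ASCII rasters together
    with household and metrics tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    EBImage,
    lhs,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
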