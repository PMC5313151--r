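Package: compsd
Title: Competition-Revised Potential Species Distribution Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps potential tree-species distributions (PSD) from closed-form
    abiotic response kernels (photosynthetically active radiation, soil water
    content, growing degree days), revises those maps by upscaling
    interspecific-competition outcomes simulated with an individual-based
    forest gap model of the JABOWA family, and assesses map accuracy against
    plot observations with overall agreement and Cohen's kappa. Includes a
    seeded synthetic-landscape generator so the full pipeline is testable
    end to end, lightweight ESRI ASCII raster input/output, and a subcommand
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
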