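Package: invertasome
Title: Structural Modeling and DNA Topology of the Hin Recombinational Enhancer Complex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling the site-specific DNA inversion machinery of
    serine invertases: reconstruction of three-dimensional duplex DNA models
    from base-pair step parameters (including the Fis-bound recombinational
    enhancer), constraint-guided rigid-body docking of recombinase and
    activator subunits into the three invertasome assembly states,
    crosslinker and tethered-nuclease (FeBABE) consistency scoring, and
    simulation of the subunit-rotation strand-exchange mechanism on branched
    supercoiled substrates with exact computation of writhe, linking-number
    change, signed node counts, and knot determinants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    Biostrings
Config/testthat/edition: 3
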