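Package: ompisland
Title: Supramolecular Outer-Membrane Protein Island Modelling and Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Constructive modelling and quantification of supramolecular
    outer-membrane protein (OMP) islands in the Gram-negative outer membrane.
    Builds porin lattices under geometric and compositional constraints
    (kagome-type hexagonal scaffolds of OmpF trimers hosting guest barrels),
    populates an asymmetric bilayer with annular lipopolysaccharide (LPS)
    shells and bulk lipids, counts LPS-mediated OMP-LPS-OMP bridges and
    extrapolates them to whole-cell numbers, computes mass budgets and
    near-neighbour distance statistics, simulates simplified 2D membrane
    dynamics with dual-cutoff lipid-protein residence/occupancy statistics
    and hexatic order metrics, and provides synthetic-image quantification:
    prominence-based maxima detection, difference-of-Gaussians bandpass
    filtering, cell normalisation, and single-fluorophore photobleaching
    copy-number estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
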