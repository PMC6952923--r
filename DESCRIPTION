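Package: miRTorus
Title: Hydrogen-Bond-Site Scoring of miRNA Sequences on a Torus Geometry
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Encodes RNA sequences as ternary vectors of partial charges at
    the three hydrogen-bonding sites of each nucleobase, lays the sequence on
    a circle (torus model) in three base orientations, and scores it with
    four functions: per-site vector size (VS), per-site charge sum (Sum), the
    electric field at the torus centre (EV_C), and the electric field summed
    over an 11x11x11 lattice spanning the structure (EV_S). Scores multiplied
    by fold-change expression values (SMEL) feed pairwise axis regressions
    whose slope intervals (slope +/- k standard errors) discriminate disease
    panels. Includes duplicate/uniqueness analysis of score vectors, a
    descending-gap fold-change outlier filter, a seeded synthetic study
    generator, file readers/writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Software, Regression, Classification, SequenceMatching
RoxygenNote: 7.3.3
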