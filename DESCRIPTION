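Package: ShiftForge
Title: Automated Construction and Training of Protein NMR Chemical Shift
    Predictors from Structure and Shift Archives
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An automated pipeline that turns paired protein structures
    (PDB format) and chemical shift lists (NMRStar 2.1/3.1) into a
    filtered, feature-annotated atomic property table held in a two-table
    SQLite store, trains one random-forest regression model per atom
    super class on semi-classical (random coil, ring current, electric
    field, hydrogen bond), sequential, structural, force-field and
    experimental features, evaluates the models by root-mean-square error
    and Pearson correlation, and applies them to new structures to emit
    per-atom predicted shifts as CSV. Includes fault-tolerant NMRStar
    parsing, PDB/NMRStar atom-name conversion, homology culling and
    structure-quality filtering, and a synthetic-fixture generator that
    builds toy proteins with known ground-truth shifts for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    DBI,
    RSQLite,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
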