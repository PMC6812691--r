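Package: raftr
Title: Shore-Based and GPS-Based Analysis of Seabird Rafting Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for studying rafting behaviour of colonial
    seabirds (flocks sitting on the sea surface near the breeding colony).
    Converts clifftop inclinometer/compass sightings into georeferenced raft
    positions, classifies GPS tracks into rafting and flying states with a
    two-component normal speed mixture fitted by expectation-maximisation,
    tests wind-direction effects with circular statistics
    (Jammalamadaka-Sarma correlation, von Mises fits), regresses raft size
    on wind speed by generalized least squares with moving-average residual
    correlation nested within day, and estimates diel trends with cyclic
    penalized smooths. Includes seeded synthetic-data generators with known
    ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    nlme,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
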