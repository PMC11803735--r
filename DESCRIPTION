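Package: strobescreen
Title: Behavioral Profiling Insecticide Screens in Larval Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotype-first insecticide screening built around
    larval zebrafish behavioral batteries recorded in multiwell plates.
    Implements frame-differencing motion-index quantification from video
    frame stacks, strobe-response scoring with solvent-null hit calling,
    behavioral-profile classification and 2-D embedding, Tanimoto
    fingerprint clustering for chemotype triage of screening hits,
    voltage-clamp percent-block quantification with rundown correction,
    and log-logistic LC50 estimation from insect diet-assay mortality.
    Includes seeded synthetic-data generators that emulate the full
    experimental structure so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml,
    jsonlite,
    tiff,
    randomForest,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
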