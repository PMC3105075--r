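Package: rumencazy
Title: CAZyme Annotation and Profiling for Rumen Eukaryotic Metatranscriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing eukaryotic metatranscriptomes from herbivore
    gut communities, with a focus on plant cell wall degrading enzymes.
    Provides non-coding RNA read filtering by alignment thresholds, top-hit
    taxonomic binning with lowest-common-ancestor tie resolution,
    carbohydrate-active enzyme (CAZy) module annotation through a staged
    Pfam-model-to-family association procedure, expression and coverage
    summarisation, comparative glycoside hydrolase family profiling with
    Pearson-distance UPGMA clustering, and collector's-curve rarefaction.
    Includes a deterministic synthetic community generator with planted
    truth so the whole pipeline can be exercised and validated without
    external databases or search tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
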