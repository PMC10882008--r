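Package: immunoclock
Title: Immune Repertoire, Signature and Molecular-Clock Analysis of
    Sequential Tumor Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracking immune escape across sequential and
    parallel multiregion tumor samples: T cell receptor (TCR) repertoire
    diversity, Morisita-Horn overlap and Levenshtein distance-1 similarity
    networks; immune gene-signature scoring with inflamed/desert/excluded
    immunophenotype classification; subclonal diversity, tumor mutational
    burden and neoantigen filtering; and a mutation/neoantigen
    molecular-clock analysis that places copy-number gains and somatic
    mutations on a relative 0-1 timeline.  Seeded synthetic-data
    generators with planted ground truth are included for every analysis
    stage, together with a pipeline orchestrator that runs the full
    simulate-analyse-integrate workflow reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
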