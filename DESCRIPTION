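Package: imprintfate
Title: Germline Differentially Methylated Regions and Their Developmental Fate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genome-wide screen for germline differentially methylated
    regions (gDMRs) from per-CpG bisulfite methylation calls, and a tracker
    for their fate after fertilization. Gamete methylomes (sperm, oocyte)
    are scanned with 25-CpG sliding windows, opposing-state regions are
    intersected into maternal and paternal gDMRs, and each gDMR is followed
    through blastocyst, placenta and a somatic-tissue panel to classify it
    as a ubiquitous imprint candidate, a placenta-specific (transient)
    imprint, tissue-restricted, or reprogrammed. Includes staging logic for
    allele-specific expression trajectories across preimplantation
    development, a synthetic methylome generator with ground-truth
    manifests, and tidy tabular interfaces throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
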