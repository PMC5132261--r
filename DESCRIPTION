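Package: cospec
Title: Co-Enrichment Analysis of MudPIT Spectral-Count Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies proteins co-enriched with a bait complex from
    multidimensional protein identification technology (MudPIT) spectral-count
    data. Provides randomized (decoy) database construction and in-silico
    tryptic digestion, DTASelect-style peptide-spectrum-match filtering with
    target-decoy false discovery rate estimation, distributed spectral
    counting (dSpC) and distributed normalized spectral abundance factors
    (dNSAF), a dual-criteria co-enrichment classifier combining salt-step
    fractionation and immunoprecipitation evidence, a ground-truthed
    synthetic-data generator for benchmarking, and object-based
    puncta-colocalization scoring for fluorescence image stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
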