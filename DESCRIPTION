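Package: hcdr3
Title: Heavy-Chain CDR3 Loop Profiling and Clonal Expansion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing immunoglobulin heavy-chain CDR3 (H-CDR3)
    repertoires from AIRR-style rearrangement tables: extraction of the
    H-CDR3 loop from the IMGT junction, clonotype grouping and expansion
    classification with squarified treemap landscapes, D-segment
    reading-frame assignment, physicochemical profiling (net charge at a
    given pH, GRAVY hydropathy, six-factor descriptor vectors), population
    comparisons (Mann-Whitney U with Bonferroni correction) and principal
    component analysis of population-mean profiles. Includes a seeded VDJ
    recombination simulator that emits annotated repertoires with ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
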