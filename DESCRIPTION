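Package: taxnog
Title: Gene-Content Bacterial Taxonomy from Taxon-Specific Orthologous Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds rank-wise databases of taxon-specific orthologous groups
    (NOGs) from annotated reference genomes, assigns taxonomy to query genomes
    by hierarchical maximum-match descent with a look-ahead disambiguation rule
    when the runner-up taxon matches at least 30 percent as well as the best,
    and quantifies functional-category overabundance in taxon-specific gene
    sets.  Includes adapters for best-hit tabular alignment output and
    gene-to-NOG tables, a synthetic taxonomy simulator for benchmarking, and
    tidy tibble-based interfaces throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
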