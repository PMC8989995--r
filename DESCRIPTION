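Package: asvref
Title: ASV-Resolved Full-Length 16S rRNA Reference Databases and Community Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build amplicon sequence variant (ASV) resolved full-length 16S
    rRNA gene reference databases with identity-threshold taxonomy and de novo
    placeholder names, evaluate reference databases against short-read amplicon
    data (high-identity coverage and classification rates with a bootstrap
    k-mer classifier), and profile microbial communities of wastewater
    treatment plants: core and conditionally rare-or-abundant taxa, primer
    bias, alpha and beta diversity, distance decay and PERMANOVA. Includes a
    seeded synthetic-community generator with known ground truth so the whole
    workflow can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    Matrix,
    vegan,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
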