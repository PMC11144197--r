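Package: telovar
Title: Telomere Variant Repeat Quantification and In Vivo Telomerase
    Processivity Estimation from Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies a variant telomere repeat (TTAGGT) alongside the
    canonical TTAGGG repeat in short sequencing reads, estimates in vivo
    telomerase repeat-addition processivity from the distribution of
    consecutive-repeat run lengths under a two-allele re-association
    model, and classifies the 3' terminal permutation of telomeres from
    C-tailed sequencing reads. Includes a synthetic read generator that
    emulates the statistical structure of telomeric whole-genome
    sequencing and C-tail terminal libraries, so that every stage of the
    pipeline can be exercised and validated without access to protected
    human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    stringi,
    tibble,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
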