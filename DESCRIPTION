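Package: phageneck
Title: Detection and Classification of the Head-Neck-Tail Module in Tailed Bacteriophages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the proteins of the bacteriophage head-neck-tail module
    (major capsid protein, large terminase, portal, adaptor, head-closure,
    neck, tail-completion, major tail and sheath proteins) from ordered phage
    proteomes and profile-profile homology evidence. Remote homologs are
    recovered by iterative seed expansion at a strict probability threshold,
    then extended at a relaxed threshold under gene-context constraints
    learned as inter-gene distance statistics. Phages are assigned one of
    four neck architecture Types, their morphological family is inferred,
    and phages of a Type are clustered by WPGMA on a similarity score that
    combines homology probability with sequence identity. Includes a
    ground-truthed synthetic universe generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
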