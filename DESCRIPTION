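Package: ervkit
Title: Mining, Annotation and Molecular Dating of Endogenous Retroviruses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterizing gammaretrovirus-like endogenous
    retroviruses (ERVs) in genome assemblies: seed-based mining of
    proviral loci with flank extraction, reference-guided structural
    annotation (LTR pairs, target-site duplications, gag-pro-pol-env
    genes, late-domain and CETTG motif states, ORF intactness,
    diagnostic deletions), majority-rule consensus construction per
    subgroup, LTR indel fingerprinting and clade assignment, and
    insertion-age estimation from CpG-masked Kimura 2-parameter
    distances between paired LTRs (T = D / (2 M)) or between genes and
    their subgroup consensus. A germline-colonization simulator plants
    proviruses of known age, subgroup and feature content into a
    synthetic host genome so that every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    phangorn,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
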