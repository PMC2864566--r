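Package: unipseudo
Title: Discovery, Dating, and Population Analysis of Unitary Pseudogenes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A comparative-genomic toolkit for detecting genes disabled in
    situ with no surviving functional copy (unitary pseudogenes). Provides a
    synthetic-genome simulator with planted truth, a translated-seed protein
    to genome mapper, exon-guided frameshift-aware spliced alignment with
    disruption calling (premature stops, frameshifts, splice-site mutations,
    truncations), a locus filter cascade with synteny and tandem-family
    checks, Dollo placement of shared disruptive mutations on a dated
    species tree, a Ka/Ks-based nonfunctionalization-time estimator,
    Hardy-Weinberg and F_ST permutation analyses for polymorphic pseudogenic
    alleles, and GO/Pfam over-representation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
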