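Package: polyar
Title: Prediction of pre-mRNA 3'-End Cleavage/Polyadenylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-class linear-discriminant recognizer for pre-mRNA
    cleavage/polyadenylation (poly(A)) sites in mammalian genomic DNA.
    Poly(A) regions are grouped into PAS-strong, PAS-weak and PAS-less
    classes by the polyadenylation-signal hexamer present upstream of the
    cleavage site; each class is recognized by a linear discriminant
    function over position-weight-matrix motif scores (PAS, cleavage-site
    and GU/U-rich downstream elements), pentamer-composition Bayes scores
    and motif-distance frequencies. Includes training from FASTA plus
    cleavage-site truth tables, genome scanning with cascade
    classification and 100-bp resolution rules, accuracy evaluation
    (sensitivity, specificity, Matthews correlation), a synthetic-corpus
    generator for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
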