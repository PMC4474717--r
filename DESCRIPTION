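Package: idrcrf
Title: Intrinsically Disordered Region Prediction with Conservation
    Profiles and Conditional Random Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts intrinsically disordered regions (IDRs) of proteins
    from sequence. Residues are labeled with a three-state alphabet
    (order, near-disorder, disorder) derived from missing backbone
    C-alpha annotations; per-position multi-class conservation profiles
    are computed from local-alignment hits against a knowledge database
    of structurally annotated sequences; a linear-chain conditional
    random field over the conservation profile and one-hot predicted
    secondary structure tags each residue, and threshold-based decision
    schemes reduce the three-class posterior to binary order/disorder
    calls. Includes CASP-style evaluation (sensitivity, specificity,
    balanced accuracy, Matthews correlation, weighted score, AUC,
    per-chain bootstrap standard errors), a synthetic corpus generator
    with a built-in local aligner, and a file-based pipeline with a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
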