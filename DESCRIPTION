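Package: perturbkit
Title: Perturbation Genomics Toolkit for CRISPRi Screens, Perturb-Seq and
    Single-Nuclei Multiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scoring and hit calling for dual-sgRNA CRISPRi growth and
    treatment-response screens (gamma/rho phenotypes, non-targeting-control
    pseudo-gene empiric false discovery rates), single-cell Perturb-seq
    analysis (guide assignment, pseudobulk knockdown quantification, module
    scoring, hurdle-style differential expression), and joint single-nuclei
    ATAC + RNA + CRISPRi perturbation analysis (hypergeometric guide
    assignment, fragment-level quality control, promoter gene-activity
    scores, background-matched motif-deviation z-scores, logistic-regression
    differential accessibility, flank-normalized meta-profiles). Ships
    synthetic-data generators with ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
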