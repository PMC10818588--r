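Package: peplogo
Title: Logo Models for Peptide-Protein Binding Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds 'logo models' -- quantitative matrices of normalized
    positional amino-acid frequencies -- from sets of equal-length peptide
    binding cores, and uses paired binder/non-binder matrices to classify
    peptides by binding score (BS) versus non-binding score (NBS).
    Includes a combinatorial non-binder pool defined by per-position
    non-preferred residue sets with seeded sampling and train/test
    exclusion, variable-length peptide scoring by 9-mer window scanning,
    BS/NBS confidence-ratio binning, confusion-matrix evaluation
    (sensitivity, specificity, accuracy), and packaged reference models
    for HLA-DQ2.5 and HLA-DQ8.1, the class II proteins that present
    gluten-derived peptides in celiac disease.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    rlang,
    tibble,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
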