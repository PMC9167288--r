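Package: editaudit
Title: Genome-Wide Specificity Audit of CRISPR-Cas9 and TALEN Editing in
    Clonal Haploid Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for auditing the genome-wide specificity
    of site-directed nucleases (CRISPR-Cas9 and TALEN) in clonal haploid
    plant systems such as Physcomitrium patens. Provides mismatch-tolerant
    prediction of candidate off-target loci (including paired TALEN
    half-site search under FokI spacer constraints), hard filtering of
    multi-sample variant calls with a haploid allele-fraction rule,
    lineage-aware attribution of every variant to polymorphism, spontaneous
    mutation, treatment effect or nuclease activity, classification of
    on-target indels by repair-pathway signature (microhomology-mediated
    alternative end joining versus classical non-homologous end joining),
    and summary statistics for mutation efficiency and group comparisons.
    A truth-labelled synthetic-experiment generator emulating clonal
    wild-type lineages, PEG-transfected controls and edited regenerants
    makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
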