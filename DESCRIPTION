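Package: oralcyto
Title: Automated Whole-Slide Oral Exfoliative Cytomorphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated digital cytomorphometry of oral mucosal smears: slide
    tiling, tissue masking and tile quality control, CIELAB K-means
    nucleus/cytoplasm segmentation with morphological refinement, per-cell
    nucleus-to-cytoplasm (N/C) ratio computation and case-level median
    aggregation. Includes a synthetic May-Grunwald-Giemsa smear and cohort
    generator with ground-truth compartment masks for end-to-end validation,
    and the nonparametric statistical battery used for exposure studies
    (Mann-Whitney U with Cliff's delta and bootstrap confidence intervals,
    Fisher's exact test with odds ratios, Spearman rank correlation with
    Fisher-z intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
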