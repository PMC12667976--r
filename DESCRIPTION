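Package: mavemap
Title: Sort-Seq Variant Effect Maps with Clinical Evidence Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and interpreting missense variant effect
    maps from sort-seq (FACS + tile sequencing) experiments. Turns
    variant count tables from select and non-select cell pools into
    rescaled functional scores with standard errors, calibrates scores
    into log likelihood ratios of pathogenicity and ACMG/AMP
    functional-evidence strengths via two-class kernel density
    estimation, benchmarks maps against clinical reference variants
    with balanced precision-recall analysis, and relates diploid
    combined-allele genotype scores to patient phenotypes. Includes a
    ground-truthed sort-seq simulator so the whole pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
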