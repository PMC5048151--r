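Package: cryptax
Title: Integrative Delimitation of Cryptic Species from Morphometric and
    DNA-Barcode Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for integrative taxonomy of cryptic species complexes,
    built around the workflow used for parasitoid wasps of the Encyrtus
    sasakii complex: per-character descriptive statistics with Tukey HSD
    post-hoc comparisons, multivariate ratio analysis (isometric size,
    shape PCA, PCA and allometry ratio spectra with bootstrap confidence
    intervals, and an LDA ratio extractor scored by standard distance),
    landmark-based geometric morphometrics (TPS input/output, generalized
    Procrustes analysis, PCA and canonical variate analysis, covariance
    matrix correlation permutation tests), and distance- plus
    character-based DNA barcoding (p and Kimura 2-parameter distances,
    haplotype collapsing, barcode-gap detection, neighbor-joining trees
    with bootstrap support, pure diagnostic characters). A synthetic data
    generator with planted three-species structure provides a ground-truth
    test surface, and a configuration-driven pipeline stitches the stages
    into one reproducible run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
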