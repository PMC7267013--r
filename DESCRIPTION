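Package: leafscan
Title: Elliptic-Fourier Shape Mapping of Leaf Outlines to QTLs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci (QTLs) that control
    whole-leaf shape in clonally replicated tree populations sampled from
    contrasting environments. Leaf outlines are resampled to equal-angle
    landmarks, superimposed by generalized Procrustes analysis, averaged per
    clonal line, and summarized by elliptic Fourier descriptors. Per-SNP
    likelihood-ratio tests contrast genotype-specific elliptic Fourier mean
    contours under a multivariate normal likelihood with AR(1)-structured
    landmark covariance; genome-wide significance comes from permutation
    thresholds computed separately for testcross and intercross markers.
    Significant QTLs are classified into length, width, blade-tip and
    blade-base shape patterns and tabulated as genotype effects across
    populations. Companion population-genetic utilities provide SNP quality
    filtering, exact Hardy-Weinberg tests, Weir-Cockerham FST, migrant number
    Nm, and QST from deme variance components, plus a synthetic-data generator
    (Balding-Nichols divergence, planted shape QTLs of each pattern class)
    with known truth for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
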