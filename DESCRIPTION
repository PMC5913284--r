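Package: memaphen
Title: Microenvironment Microarray Single-Cell Phenotype Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies marker-positive subpopulations of epithelial cells cultured
    on combinatorial microenvironment microarrays (MEMA). Provides the full chain
    from multichannel spot images to biology: histogram-mode background thresholding
    and subtraction, marker-based watershed segmentation of nuclei, per-cell
    intensity and morphology features, reference-condition (COL4) mean + k*SD gating
    of AXL+/cKIT+ cells, binomial-logit generalized linear models that decouple
    additive microenvironment component effects with single-step Tukey-type post-hoc
    contrasts, condition-level z-score clustering and t-SNE embedding, and
    downstream assay calculators (2^(-ddCt) fold change, four-parameter logistic
    IC50, EdU proliferation fractions). A synthetic MEMA generator with known ground
    truth makes every stage testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    multcomp,
    mvtnorm,
    Rtsne,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
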