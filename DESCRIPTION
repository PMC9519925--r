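Package: imgtx
Title: Imaging Transcriptomics of Sex-Specific Functional Connectivity
    Alterations
Version: 0.1.0
Authors@R:
    person("imgtx", "maintainers", email = "imgtx@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline linking regional cortical gene
    expression to sex-specific resting-state functional-connectivity (rsFC)
    abnormalities in depression. Provides donor-microarray-to-parcellation
    expression mapping, ComBat site harmonization, factorial group contrasts
    with FDR control, NIPALS partial least squares regression with bootstrap
    loading-weight stability, spatially constrained spin-permutation nulls,
    cross-validated reproducibility testing with the corrected resampled
    t-test, preranked gene-set enrichment, genotype-based validation via
    risk-allele scores, and power/classifier simulations. Every input can be
    generated synthetically with recorded ground truth for parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
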