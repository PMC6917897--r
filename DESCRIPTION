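Package: brainsig
Title: Spatial Gene-Signature Discovery from Imaging Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised discovery of gene signatures associated with a
    cognitive function from point-sampled brain transcriptomes and volumetric
    functional-association maps. Implements background filtering and
    differential-stability probe selection, per-donor compartment-wise
    normalization, co-registration of expression samples with a z-score term
    map (positive-z masking and spherical smoothing), per-donor spatial
    correlation combined by approximate random effects into ranked gene
    lists, weighted pre-ranked gene-set enrichment with a gene-tag
    permutation null and sign-stratified FDR, leading-edge candidate
    ranking, cortical/subcortical overlap analysis with hypergeometric
    over-representation, and validation statistics (evidence-weighted
    precision scores, sampling-without-replacement chance probabilities, and
    bootstrap tests on correlation differences). Ships a synthetic-data
    generator with planted ground truth so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
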