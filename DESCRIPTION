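Package: petrad
Title: PET Radiomics of the Primary Tumour for Nodal Metastasis Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiomic analysis of FDG-PET primary-tumour uptake for predicting
    lymph-node metastases in endometrial cancer. Provides NIfTI volume and
    mask handling, a synthetic tumour/cohort generator, iterative-threshold
    tumour segmentation, a 44-feature radiomic extractor (SUV, shape,
    histogram and five 3D texture-matrix families after 64-level
    quantization), univariate screening with Youden cut-offs and
    leave-one-out assessment, Spearman-gated feature reduction with stepwise
    backward neural-network model selection, a 200-run averaged network
    ensemble, and a unified prognostic framework that OR-combines radiomic
    prediction with visual nodal detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
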