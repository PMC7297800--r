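Package: periprog
Title: Voxel-Wise Radiomics Mapping of Peritumoral Progression in Glioblastoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to identify future tumour-progression areas in the
    peritumoral non-enhancing region of glioblastoma from preoperative
    multimodal MR maps (T1C, FLAIR, ADC, FA, DTI-p, DTI-q, rCBV).
    Provides peritumoral ROI construction via spacing-aware distance
    transforms (progression ROI by subtraction of the contrast-enhancing
    lesion, 5/10/15/20 mm non-progression shells, contralateral NAWM
    control), diffusion-tensor isotropic/anisotropic (p/q) decomposition,
    a 294-feature voxel-wise radiomics extractor (first-order histogram
    statistics plus GLCM and GLRLM texture features over a local cubic
    neighbourhood, compiled), a feed-forward binary classifier trained by
    scaled conjugate gradient on cross-entropy with probability heat-map
    output and external-validation reports, paired-t group comparisons of
    ROI means, and a seeded synthetic multimodal phantom generator so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
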