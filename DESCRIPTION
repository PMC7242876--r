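Package: adipophen
Title: Quantitative Adipose Phenotyping from Micro-CT, Histology, PET and
    Indirect Calorimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quantification pipelines for murine cardiometabolic
    phenotyping studies. Implements Hounsfield-threshold body-fat segmentation
    on whole-body micro-CT with partial-volume correction at air/tissue
    interfaces, adipocyte morphometry and size-frequency analysis on H&E
    fields, percent-area scoring of picrosirius red and DAB stains, brown-fat
    FDG-PET uptake (%ID/g) with shape-based interpolation of sparse axial ROI
    contours, gamma-count uptake and PET-vs-gamma agreement regression,
    light/dark partitioning and energy-expenditure summaries of indirect
    calorimetry traces, and relative qPCR (delta-delta-Ct) and blot
    densitometry normalization. Ships deterministic synthetic phantom
    generators with machine-readable ground truth for every stage, so the
    whole pipeline is testable end to end without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
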