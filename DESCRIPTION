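Package: gemquant
Title: Quantification of Encapsulin (GEM) Tag Labeling in Cryo-ET and
    Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify labeling of cellular targets by genetically
    encoded multimeric (GEM) encapsulin tags. Provides postprocessing of
    particle-detection probability maps from cryo-electron tomograms
    (thresholding, lamella masking, size-filtered connected components),
    curation accounting, particle-to-structure surface distances via a 3D
    Euclidean distance transform, volumetric fold-enrichment (relative
    labeling index), fluorescence colocalization and recruitment-kinetics
    statistics (Kruskal-Wallis with Dunn's baseline comparisons), and
    single-exponential FRAP recovery fitting. A seeded synthetic-data module
    generates tomographic scenes with ground truth, probability maps,
    recruitment timecourses and FRAP traces for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
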