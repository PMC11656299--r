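Package: CTDenoiseBench
Title: Benchmarking Toolkit for Low-Dose CT Image Denoising
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end evaluation framework for low-dose computed
    tomography (CT) denoising algorithms. Provides paired high/low-dose scan
    simulation via parallel-beam projection, projection-domain Poisson noise
    insertion and filtered back projection; full-reference image quality
    metrics (SSIM, PSNR, RMSE, VIF) and physical CT metrics (CNR, CT-number
    accuracy, line profiles); radiomic feature extraction on organ masks and
    a radiomic feature similarity score; sequential model-based
    hyperparameter optimization with a Gaussian-process surrogate and
    expected improvement; a denoiser plugin interface with desk-scale
    reference denoisers; and the statistical comparison machinery
    (patient-level splits, weighted sampling, hard-slice subsets,
    Mann-Whitney and Wilcoxon tests, competition ranking).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
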