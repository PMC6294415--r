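Package: tonocore
Title: Tonotopic Map Analysis and Auditory Core Delineation on Cortical Flat Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of tonotopic maps and delineation of the
    auditory core on flattened cortical patches. Provides the ERB-number
    (Cam) cochlear frequency scale, unbiased preferred-frequency estimation
    from voxel tuning curves via matching against a bank of hypothetical
    Gaussian tuning curves, tuning-width fitting, GLM-based estimation of
    responses to sparse-fMRI tone stimulation with adaptive FDR voxel
    selection, Sobel gradient fields with automated gradient-reversal
    detection and clustering, ROI geometry in a Heschl's-gyrus-aligned
    coordinate frame, circular and axial statistics with one-sample
    Hotelling T-squared consistency testing, quantitative-MRI myelin map
    conditioning, and a synthetic-cohort generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
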