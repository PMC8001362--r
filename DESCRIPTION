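Package: steatoquant
Title: Automatic Quantification of Macrovesicular Steatosis in Sudan-Stained Liver Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-level supervised classification of Sudan-stained frozen liver
    sections into fat-vacuole and non-vacuole classes from six-channel
    RGB + CIE L*a*b* color features, watershed separation of confluent vacuoles,
    a nucleus-derived macrovesicle size filter, and reporting of the
    macrovesicular steatosis (ME) percentage. Includes magnification-based
    spatial calibration, reference histogram matching, six interchangeable
    classifier backends (KNN, SVM, random forest, naive Bayes, and two neural
    networks including a minimal built-in dense network), pixel-wise mask
    validation metrics, benchmarking harnesses, and a synthetic stained-slide
    generator with pixel-exact ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    class,
    e1071,
    grDevices,
    jsonlite,
    parallel,
    png,
    randomForest,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jpeg,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
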