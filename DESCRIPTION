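Package: groupcapsnet
Title: Grouped Capsule Networks for Hemorrhage Segmentation in Head CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates grouped convolutional capsule
    networks for binary segmentation of hyperdense (hemorrhage-like) lesions
    in non-contrast head CT slices. Capsule types are partitioned into
    disjoint equal groups so that voting and dynamic routing are confined
    within each group, cutting the number of intermediate vote capsules and
    trainable transformation matrices by the group count. Includes both the
    classic squashing nonlinearity and a cheaper modified variant, a
    U-shaped encoder-decoder constructor with analytic parameter and vote
    counting, Hounsfield-unit windowing and slice preprocessing for CT
    volumes, a phantom generator producing CT-like slices with exact lesion
    masks, pixel-overlap evaluation metrics, and patient-level k-fold cross
    validation with model ensembling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
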