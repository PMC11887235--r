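Package: logstage
Title: Self-Supervised T-Staging of Grayscale MRI Slices with
    Laplacian-of-Gaussian Filtering and Information-Bottleneck Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for staging rectal-cancer MRI slices without manual
    labels.  Grayscale 2D slices (extracted from NIfTI volumes or DICOM
    series) are texture-enhanced with a zero-sum Laplacian-of-Gaussian
    filter, encoded by a small convolutional backbone, and clustered with
    a sequential information-bottleneck algorithm that maximizes
    I(T;Y) - I(T;X)/lambda via a draw-and-merge strategy with
    Jensen-Shannon merger costs.  Cluster assignments serve as
    pseudo-labels in an alternating cluster/train loop; the resulting
    four-way classifier is evaluated with one-vs-rest accuracy,
    sensitivity, specificity, balanced accuracy and ROC/AUC under
    patient-grouped k-fold cross-validation.  A synthetic staged-phantom
    generator makes the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    RNifti,
    stats,
    utils,
    withr
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
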