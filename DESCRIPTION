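Package: sphereMML
Title: N-Spherical Minimalist Machine Learning Classification
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary classification of high-dimensional numeric data with the
    N-spherical minimalist machine-learning model: per-attribute T-means
    thresholds rank attributes by univariate error counts, an orientation
    criterion decides whether the positive class lies inside or outside a
    radial frontier, and nested progressive attribute sets each contribute a
    spherical decision boundary whose votes classify new patterns. Includes
    differential-evolution self-adjustment of the two hyperparameters,
    deterministic leave-one-out cross-validation with balanced accuracy and
    F1, Friedman mean-rank and Holm post-hoc comparison of classifiers over
    many datasets, seeded synthetic-data generators (concentric radial
    shells, imbalanced Gaussian clouds, missing-value injection), CSV/ARFF
    readers and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    foreign,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
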