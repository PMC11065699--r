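Package: qimb
Title: Deep Q-Learning for Classification Under Extreme Class Imbalance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Casts classification as a Markov decision process and trains a
    dueling double deep Q-network whose reward is inversely proportional to
    class frequency, so that minority classes carry as much learning signal
    as majority classes. Episodes terminate when a minority-class sample is
    misclassified, coupling actions to future reward. Includes a synthetic
    imbalanced Gaussian-mixture data generator, feed-forward and
    gradient-boosting comparator classifiers with cost-sensitive weighting,
    and a balanced-classification evaluation panel: sensitivity,
    specificity, precision, F-measure and G-mean (geometric-mean variants),
    AUROC with Hanley-McNeil confidence intervals, sensitivity-targeted
    decision-threshold adjustment, and one-vs-all multi-class reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    xgboost,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
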