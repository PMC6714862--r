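Package: stsbssvm
Title: Cross-Subject EEG Emotion Recognition with Significance-Test
    Filtering and Sequential Backward Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-class (positive/negative valence) emotion
    recognition from multichannel EEG across subjects.  Extracts ten
    linear and non-linear features per channel (Hjorth activity, mobility
    and complexity, standard deviation, Welch band power in the theta,
    alpha, beta and gamma rhythms, sample entropy and wavelet entropy)
    into a high-dimensional trial-by-feature matrix, screens columns with
    a two-sample significance test (Student's t or Kolmogorov-Smirnov,
    chosen by a majority normality vote), refines the retained set by
    SVM-wrapped sequential backward selection, and evaluates everything
    under leave-one-subject-out cross-validation together with common
    baseline classifiers.  Includes a synthetic EEG generator with
    controllable class effects, per-subject amplitude offsets and 1/f
    background noise so the full pipeline is testable without
    license-gated recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    e1071,
    class,
    randomForest,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
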