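Package: ltschange
Title: Forest Change Classification from Irregular Landsat Time Series and
    Local Expert Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated pipeline for monitoring deforestation and forest
    degradation from irregular Landsat-like surface reflectance time series
    combined with geo-tagged disturbance reports from local experts.
    Computes spectral indices and tasseled-cap transforms, fits robust
    (M-estimator) season-trend models per time-series segment, detects at
    most one structural break per pixel series by a BIC scan, derives six
    spectral-temporal metrics per band, trains random-forest change
    classifiers with out-of-bag error reporting and vote-fraction class
    probabilities, scores per-band importance by averaged normalized ranks
    of single-band model accuracies, runs a phased iterative model-updating
    protocol, and maps per-class change probabilities behind a baseline
    forest mask. A synthetic-data generator with known ground truth drives
    testing and simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
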