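Package: auscultr
Title: Detection and Classification of Adventitious Breath Sounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An auscultation-audio analysis toolkit for pediatric lung sounds.
    Implements rule-based detection of crackles (transients shorter than 20 ms
    whose peak magnitude exceeds twice the average magnitude) and wheezes
    (sustained narrowband events longer than 500 ms found with a 160 ms peak
    window over a 200 ms Hamming-smoothed envelope), wavelet-packet-decomposition
    features, a three-class support vector machine at recording granularity, a
    triple-rater gold-standard consensus procedure with expert adjudication, and
    the full evaluation suite (confusion matrices, per-class sensitivity,
    precision, specificity and F1, weighted Cohen's kappa with confidence
    intervals, Kendall's coefficient of concordance, chi-square tests). A seeded
    synthetic auscultation simulator with ground-truth event logs supports
    end-to-end pipeline evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml,
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
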