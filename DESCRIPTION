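Package: circaBench
Title: Synthetic Benchmarking and Exact Nonparametric Detection of
    Biological Rhythms in Omics Time Series
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking genome-scale rhythm detection. Generates
    synthetic circadian expression time series with known ground truth
    (uniform phases, uniform period and amplitude within user ranges, additive
    Gaussian noise, optional outlier spikes), detects rhythmicity with a
    JTK-style rank test using exact tie-aware Kendall null distributions over
    a grid of cosine reference templates, estimates mesor, amplitude, phase
    and peak-to-trough fold change by cosinor regression, and scores results
    against the simulated truth. Includes the cautionary data manipulations
    (duplication and concatenation, down-sampling, truncation) whose effect on
    false-positive rates the benchmark harness quantifies, plus CSV
    import/export of datasets and results and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Software, TimeCourse, StatisticalMethod, Transcriptomics
RoxygenNote: 7.3.3
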