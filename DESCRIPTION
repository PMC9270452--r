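Package: faunabeta
Title: Biotic Homogenization Analysis for Quaternary Mammal Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies biotic homogenization (declining beta diversity) of
    fossil and modern species assemblages. Provides site vetting and time
    binning for occurrence data, incidence-based similarity metrics (Jaccard,
    corrected Forbes, Sorensen/Simpson turnover-nestedness partition in
    pairwise and multisite forms), a site-shuffling permutation null model
    with standardized effect sizes and confidence bands, age-error and
    equal-effort resampling sensitivity analyses, cluster-hull geographic
    range size and equal-area grid occupancy, climate turnover from principal
    components of gridded climate samples, a space-for-time similarity
    mapper, and a synthetic fossil-record generator with a controllable
    homogenization signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
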