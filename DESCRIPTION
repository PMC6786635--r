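Package: chemgroup
Title: Quantitative Grouping of Complex Substances from Analytical
    Chemistry Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Two complementary workflows for grouping complex substances
    (UVCBs - substances of unknown or variable composition, complex
    reaction products or biological materials) from analytical chemistry
    feature tables such as GC-MS, GCxGC-FID or IM-MS fingerprints. The
    unsupervised workflow de-noises the profile matrix by reduced-rank
    singular value decomposition, clusters samples by correlation distance
    with average linkage, and scores the agreement between the dendrogram
    and a reference categorization with the Fowlkes-Mallows index and a
    label-permutation null. The supervised workflow tunes and evaluates a
    random-forest classifier by leave-one-out cross-validation, tests its
    accuracy against a label-permutation null, ranks features by mean
    decrease in accuracy, and integrates the top-ranked features into
    ToxPi weight-of-evidence profiles. A seeded synthetic-profile
    generator with class, substance and replicate structure supports
    method evaluation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    randomForest,
    withr
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
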