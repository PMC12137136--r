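Package: sustig
Title: Adjudicating Sustained Versus Ignition Temporal Profiles in
    Trial-Structured Neural Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for testing competing predictions about
    the temporal profile of content-specific neural activity in
    trial-structured recordings: a trial-schedule and high-gamma/oscillation
    simulator with planted, recoverable structure; channel responsiveness
    and category-selectivity (d-prime) screening; duration analysis via
    BIC-compared temporal design matrices with sustained and
    offset-ignition regressors; cross-temporal representational similarity
    analysis with surrogate z-scoring and template adjudication; linear-SVM
    decoding harnesses including cross-task and temporal generalization
    with beta-binomial Bayes factors; Morlet time-frequency estimation,
    pairwise phase consistency and generalized-eigendecomposition spatial
    filters; and a shared engine for cluster-based permutation inference,
    false-discovery-rate control and Bayes-factor utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
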