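Package: aldropout
Title: Attribute Drop-Out for Active Learning with Heuristic Annotators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pool-based active learning when labels come from
    human annotators who rely on fast-and-frugal heuristics such as
    Take-the-Best or fast-and-frugal trees. Implements a closed-form
    model of the probability that a query is mislabeled when the
    annotator decides on a single attribute, an attribute drop-out
    mechanism that masks high-risk attributes before a query is shown
    to the annotator, synthetic heuristic oracles that label masked
    queries, entropy and information-density query strategies with a
    logistic-regression learner, and an evaluation harness based on the
    area under the learning curve with paired comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
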