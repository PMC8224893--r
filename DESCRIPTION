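Package: perturbsim
Title: Monte-Carlo Phenotype Simulation on Signed Pathway Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the activation or inhibition state of every node in a
    signed directed meta-pathway network given a set of up- or down-regulated
    input nodes. Synthetic log fold changes are drawn from a rectified
    Gaussian, propagated to a steady state through the network, and tallied
    over Monte-Carlo repetitions into state probabilities, log-odds activity
    scores, empirical p-values from input randomization, and Storey q-values,
    at both node and pathway level. Includes generators for synthetic test
    networks and pseudo-observed expression data, plus the benchmarking
    arithmetic (PPV, sensitivity, specificity, false negative rate) used to
    compare predictions against observed log fold changes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
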