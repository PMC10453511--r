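Package: aesgrn
Title: Gene Regulatory Network Inference by In Silico Perturbation of
    Learned Expression Simulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains one neural-network forecaster ("agent") per gene to
    predict its expression from the recent expression of all genes, composes
    the agents into a closed-loop simulator of the expression system (an
    artificial environmental setting), optionally selects per-agent
    architectures with a genetic algorithm, and infers a gene regulatory
    network by perturbing each gene in silico, converting the slopes of the
    measured responses into edge probabilities, and scoring them against a
    gold-standard network with AUC-ROC. Includes a synthetic benchmark
    generator (random directed network plus discrete-time dynamics) and
    readers/writers for DREAM-style tab-separated expression time series and
    gold-standard edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
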