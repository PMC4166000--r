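Package: panflux
Title: Gene Gain and Loss Dynamics and Supergenome Size Estimation for
    Prokaryote Genome Clusters
Version: 0.1.0
Authors@R:
    person("panflux", "maintainers", email = "panflux@example.org",
           role = c("aut", "cre"))
Description: Quantifies the dynamics of gene family gain, loss, expansion
    and reduction in groups of closely related prokaryote genomes. Fits a
    gain-loss-duplication birth-and-death model of gene family copy-number
    evolution on a rooted species tree by maximum likelihood, computes
    per-family per-branch posterior probabilities of the four event types,
    converts expected event counts to per-substitution rates with flux and
    balance summaries, and estimates the size of the supergenome (the gene
    family reservoir accessible to the group) from the spectrum of repeated
    family gains under uniform-pool and power-law-pool maximum-likelihood
    sampling models. Includes least-squares midpoint rooting, pangenome
    summaries, permutation and bootstrap statistics, and a forward Gillespie
    simulator of gene content evolution that provides ground truth for every
    inference stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
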