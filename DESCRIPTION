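Package: mnclust
Title: Multi-Network Clustering for Protein Complex Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects (possibly overlapping) protein complexes by jointly
    factorizing a protein-protein interaction network and a domain-domain
    interaction network coupled through a many-to-many domain-protein
    association matrix. The model places a Bernoulli exponential-link
    likelihood on each network, shares a single nonnegative membership
    matrix across layers, and uses automatic relevance determination
    (half-normal/inverse-gamma) priors to select the effective number of
    clusters. Includes alternating multiplicative-update inference,
    threshold-based complex extraction, the standard complex-matching
    evaluation metrics (Sn/PPV/Acc, overlap score, FRAC,
    precision/recall/F), hypergeometric functional enrichment, a
    forward-sampling synthetic-data generator with planted structure, and
    a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
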