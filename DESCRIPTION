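Package: parabuffer
Title: Genetic Buffering Between Duplicate Genes
Version: 0.1.0
Authors@R:
    person("parabuffer", "developers", email = "devnull@example.org",
           role = c("aut", "cre"))
Description: Analysis of genetic buffering (mutual backup) between paralogous
    gene pairs from quantitative genetic-interaction screens. Implements a
    best-match Gene Ontology semantic-divergence score (GO-div) with
    information-content term similarity, buffering classification with two
    randomization null protocols, Nei-Gojobori (1986) Ka/Ks estimation with
    Jukes-Cantor correction, expression divergence, neutral-decay analysis of
    buffering strength versus synonymous divergence (partial correlations,
    Gaussian kernel density mode detection, regression slope), feature-based
    prediction of backup capacity with cross-validated ROC/AUC, secondary
    structure transition-vector comparison, shared protein-interaction
    partners and protein-complex co-clustering, and a synthetic-data
    generator producing every input format the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
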