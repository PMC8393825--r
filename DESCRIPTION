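Package: rabn
Title: Reconstructability Analysis and Bayesian Network Structure Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive generation and classification of discrete graphical
    model structures from two traditions: reconstructability analysis (RA),
    whose models are undirected hypergraphs of relations fitted by maximum
    entropy, and Bayesian networks (BN), whose models are directed acyclic
    graphs fitted in closed form.  Provides the RA neutral and directed
    structure lattices, enumeration of labeled DAGs and their Markov
    equivalence ("specific") and unlabeled ("general") classes, d-separation,
    CPDAGs, an extended RA-style notation that encodes V-structure
    independencies, the joint RA-BN lattice organized by variable-adjacency
    (Rho) graphs, prediction-focused directed sub-lattices, and
    information-theoretic fitting (iterative proportional fitting, closed-form
    factorization), model comparison (likelihood-ratio tests, AIC/BIC) and
    exploratory lattice search on contingency data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
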