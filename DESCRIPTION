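Package: cheesemlp
Title: Neural-Network Quality Modeling and Formulation Optimization for
    Herb-Fortified Kombucha Fresh Cheese
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modeling the quality of herb-fortified kombucha fresh
    cheese with a multilayer perceptron (6 inputs: storage day, herb type,
    sample type; 16 outputs: chemical composition, water activity, pH,
    antioxidant capacity, microbial counts). Includes the published trained
    network (MLP 6-10-16) as a bundled weight fixture, feed-forward
    prediction, quasi-Newton (BFGS) training of new networks with
    architecture search, Yoon's connection-weight global sensitivity
    analysis, a goodness-of-fit metric suite (reduced chi-square, RMSE, MBE,
    MPE, SSE, AARD, r-squared), chemometric exploration (correlations, PCA
    with signed variable contributions, hierarchical clustering), and
    multi-objective Pareto optimization of the formulation by exhaustive
    enumeration or a seeded genetic algorithm. A factorial-design synthetic
    data generator makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
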