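Package: ffgraph
Title: Forney-Style Factor Graphs with Nested Models, Variational
    Constraints and Reference Bethe Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A builder language for Forney-style factor graphs supporting
    tilde-statement materialization, deterministic folding, compound
    unrolling, vector variables, nested submodels with missing-interface
    binding, a node-type registry with keyword aliasing, and a plugin
    system. The variational-constraints plugin resolves factorization and
    functional-form constraints to per-factor local factorizations,
    defining a Constrained Bethe Free Energy. A reference engine provides
    exact enumeration, sum-product belief propagation for discrete
    models, Bethe free energy evaluation, coordinate ascent for conjugate
    families, and exact Gaussian-chain smoothing for linear state-space
    models. Graphs serialize to JSON and render to DOT.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
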