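Package: metahgt
Title: Metapopulation Dynamics of a Horizontally Transferable Gene
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Birth-death-mutation dynamics for a metapopulation of
    horizontally transferable genes. Each population of the gene carries a
    character state (y, z): indispensability y, the number of dependencies
    its microbial host has accumulated on the gene, and connectivity z, the
    degree to which the gene product requires its current host's cellular
    milieu. Death by gene loss and birth by horizontal transfer follow
    exponential kernels in y and z with density-dependent colonization.
    Provides deterministic (expected-value) and seedable stochastic engines
    over discrete ancestor-descendant mappings, closed-form lifetime and
    elimination-time calculators, a Price-equation decomposition of the
    one-mapping change in mean character state into selection and
    transmission terms, beta-sweep experiments over colonization
    opportunity, and a command-line interface with canned experiment
    recipes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
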