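Package: floodnet
Title: Information Flow and Minimization of Signed Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes regulatory information flow ("network flood") through
    signed, weighted, directed gene regulatory networks in which flow is
    replicated rather than conserved at each node, and reduces a network to
    the sub-network that carries flood above a threshold between a set of
    active environmental signals and optional reporter (sink) genes. Provides
    the essential-walk traversal calculus with a brute-force definitional
    oracle and a scalable worklist implementation, the saturation-gadget
    network transformation and its inverse, threshold- and sink-based
    minimization, a synthetic network generator with perturbation operations
    for sensitivity analysis, hypergeometric reporter enrichment, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
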