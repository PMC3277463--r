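Package: metreconcile
Title: Reconciliation, Balancing and Comparison of Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for putting heterogeneous metabolic-model and reaction data
    on a standardized footing. Parses the common reaction-string dialects found
    in published genome-scale models, resolves metabolite identities by
    structural (canonical SMILES), lexical and phonetic evidence, detects and
    repairs elemental/charge imbalances by minimal proton/water adjustment,
    consolidates duplicate metabolites and reactions across sources, compares
    model content on canonical structure keys, audits models with flux balance
    analysis before and after standardization, exports and imports SBML with
    fbc extensions, and enumerates minimal pathways between metabolites on the
    bipartite metabolite-reaction graph. Includes a seeded synthetic-corpus
    generator that injects the classic inconsistency classes (naming variants,
    missing protons, wrong water coefficients, duplicates, R-group masking)
    with ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
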