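Package: cryptvar
Title: Cryptic Mutation-Rate Variation from De Novo Mutations and
    Coincident SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to ask how much site-to-site variation in the human
    mutation rate a predictive mutability model could be missing. Provides
    (i) a simulation framework that bins de novo mutations (DNMs) by
    mutability index (MI), fits a weighted log-linear rate model, injects
    lognormal unexplained variance into Poisson count simulations, and
    measures how often simulated correlations exceed the observed one; and
    (ii) a gamma-rate integral theory that converts an observed excess of
    human-chimpanzee coincident SNPs into the mean fold-hypermutability of
    coincident-SNP sites, with confidence intervals propagated from the
    excess. Includes synthetic-data generators for MI tracks, DNM sets
    (with optional MI-dependent under-reporting), and two-species SNP
    coincidence under mean-one gamma rate heterogeneity.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
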