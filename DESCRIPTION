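Package: gatordiet
Title: Prey Importance and Individual Diet Specialization from Stomach Contents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative stomach-content analysis for crocodilian diet
    studies. Computes the Index of Relative Importance (IRI and
    percent-IRI) per prey category, decomposes the population total niche
    width into within- and between-individual components (TNW = WIC + BIC)
    on a Shannon scale, tests the between-individual component against a
    Monte Carlo null in which every individual samples from the shared
    pooled resource distribution, and rescales the specialization index to
    an adjusted E value. Includes the study-design filters used for
    juvenile analysis sets (length cutoff, empty stomachs, recaptures,
    mono-category stomachs), a Dirichlet-multinomial diet simulator
    spanning the generalist-specialist continuum, and a two-population
    comparison report with a full filter ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
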