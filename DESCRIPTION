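Package: sfscoal
Title: Simulation-Based Composite-Likelihood Demographic Inference from
    the Site Frequency Spectrum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers demographic parameters (population sizes, divergence
    times, migration rates, growth rates, admixture proportions) from the
    observed site frequency spectrum (SFS) of one or more populations. The
    expected SFS under an arbitrary multi-population demographic model is
    estimated from structured-coalescent simulations as a ratio of branch
    lengths, a composite likelihood of the observed spectrum is maximized
    by cycles of one-dimensional (Brent) conditional maximization, and
    uncertainty is quantified by parametric bootstrap. Supports joint
    multidimensional spectra, products of pairwise composite likelihoods
    for many populations, SNP-panel ascertainment bias (sites heterozygous
    in a single individual), AIC model comparison, and a composite
    likelihood ratio goodness-of-fit test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
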