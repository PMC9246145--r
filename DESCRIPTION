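Package: codonregimes
Title: Intragenomic Mutation-Bias Regimes and Selection on Synonymous Codon Usage
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies natural selection and non-adaptive nucleotide bias acting
    on synonymous codon usage from coding sequences alone. Genes are clustered
    into candidate mutation regimes by correspondence analysis of codon
    frequencies followed by CLARA k-medoids clustering, and a Bayesian
    selection-mutation-drift multinomial model with latent lognormal gene
    expression is fit by adaptive MCMC, either with a single genome-wide set of
    mutation-bias coefficients (ConstMut) or with regime-specific mutation bias
    and shared selection coefficients (VarMut). Model variants are compared via
    predicted-expression correlations and the Deviance Information Criterion,
    and GC3 landscapes along chromosomes are summarised with 20-gene windows.
    Includes a synthetic-genome simulator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
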