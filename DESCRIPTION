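Package: mutselhet
Title: Mutation-Selection Substitution Models and Evolutionary Rate Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Site-specific mutation-selection substitution models for amino
    acid sequences and the statistics that connect them to standard empirical
    substitution matrices. Builds codon-averaged amino acid mutation models
    from the genetic code under Kimura two-parameter nucleotide mutation,
    computes site-specific substitution rate matrices from fitnesses or
    equilibrium frequency profiles, derives site-averaged exchangeability
    matrices through the covariance of site profiles, and quantifies selective
    constraint through the effective number of acceptable amino acids and the
    substitution rate relative to neutral. Estimates site profiles from
    multiple sequence alignments with Henikoff position-based weighting, and
    includes a stability-constrained ("Stokes-Fisher") Gillespie simulator of
    codon sequence evolution under selection for folding free energy, exposing
    instantaneous site-specific equilibrium frequencies and the spatial and
    temporal heterogeneity of substitution rates.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    seqinr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
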