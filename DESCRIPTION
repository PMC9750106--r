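Package: evoaccum
Title: Evolutionary Accumulation and Cancer Progression Models on Genotype Lattices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Unified engine for models of irreversible event accumulation
    inferred from cross-sectional binary data: oncogenetic trees (OT),
    conjunctive Bayesian networks (CBN), OncoBN, H-ESBCN and mutual hazard
    networks (MHN). Represents models, computes transition rate matrices and
    jump-chain transition probabilities of the continuous-time Markov chain
    on the genotype lattice, predicts genotype distributions at an
    exponential observation time, enumerates evolutionary paths with their
    probabilities, simulates cross-sectional samples with observational
    (genotyping) error, generates random models, and fits the tractable
    families (OT via maximum-weight branching, MHN via exact penalised
    likelihood, CBN rates under a fixed DAG).
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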