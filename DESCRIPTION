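Package: qtnbench
Title: Benchmarking GWAS Methods Across Simulated Genetic Architectures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates additive quantitative traits on genotype matrices
    across grids of causal-variant counts and heritabilities, runs three
    association engines (a single-marker mixed linear model with
    population-structure covariates and a kinship random effect, a
    FarmCPU-style multi-locus iterative scan, and a BayesCpi Gibbs
    sampler for whole-genome spike-and-slab regression), and scores them
    with a linkage-disequilibrium-aware power/FDR/Type-I framework at
    matched positive-call counts. Includes a structured synthetic
    population generator (Balding-Nichols differentiation, tunable LD
    decay, U-shaped or filtered allele-frequency spectra) so the whole
    benchmark runs without external genotype data, plus Bayesian
    estimation of the number of causal variants and trait heritability
    to guide the choice of association method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    Rcpp,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
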