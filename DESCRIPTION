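Package: kindyn
Title: Comparative Molecular Dynamics Trajectory Analysis for Kinase
    Conformational Selectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse molecular dynamics trajectories of kinase
    systems and compare ligand-bound against ligand-free ensembles.
    Implements structural stability metrics (Kabsch superposition, RMSD,
    RMSF), dynamic cross-correlation matrices of residue motions,
    principal component analysis with Boltzmann-inverted free-energy
    landscapes, Markov state models (implied timescales,
    Chapman-Kolmogorov validation, PCCA+ coarse-graining, mean first
    passage times), MM/GBSA binding free-energy combination with
    per-residue decomposition, and Girvan-Newman residue community
    networks weighted by motion correlation. Ships seedable synthetic
    generators (metastable Brownian dynamics, planted covariance
    displacement fields, discrete Markov chains, additive energy tables)
    so every stage is testable against planted ground truth, plus an
    end-to-end pipeline for two-system comparisons such as the open
    versus closed phosphate-binding-loop contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    igraph
Config/testthat/edition: 3
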