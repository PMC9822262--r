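Package: kinthread
Title: Potts Coevolutionary Threading of Kinase Conformational Penalties
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-based analysis of the conformational free-energy
    landscape of protein kinase catalytic domains. Threads aligned kinase
    sequences over a Potts coevolutionary Hamiltonian weighted by
    contact-frequency differences between active DFG-in and classical
    DFG-out structural ensembles, yielding a statistical-energy penalty
    for the conformational change per sequence. Decomposes the divergence
    between tyrosine-kinase and serine/threonine-kinase penalties into
    residue-pair contributions, tests it with a weighted Welch two-sample
    statistic, and calibrates the statistical-energy scale against
    reorganization free energies derived from absolute binding
    free-energy bookkeeping. Includes phylogenetic sequence weighting,
    structure contact-map extraction, a Gibbs sampler for Potts models,
    and a synthetic planted-divergence data generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    bio3d,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'kinthread-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'alignment.R'
    'contacts.R'
    'data-kinases.R'
    'stats.R'
    'potts.R'
    'threading.R'
    'synthetic.R'
    'pipeline.R'
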