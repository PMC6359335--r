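Package: accelMD
Title: Accelerated Molecular Dynamics Reweighting and Peptide Folding Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis stack for accelerated molecular dynamics (aMD)
    simulations of small peptides: boost-potential parameterisation and
    per-frame boost energies, reweighting of biased ensembles to canonical
    potentials of mean force by exponential, Maclaurin-series and
    second-order cumulant estimators, per-residue Ramachandran
    classification and PMF maps, dihedral and Cartesian principal component
    analysis with free-energy-landscape density clustering, Kullback-Leibler
    divergence convergence assessment between replicas, and backbone
    hydrogen-bond and end-to-end-distance structural statistics. Ships a
    synthetic-system module (Metropolis samplers on analytic periodic
    potentials, ideal-geometry peptide backbone builder, boost logs) so the
    full pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    bio3d,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'accelMD-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'amd.R'
    'potentials.R'
    'toychain.R'
    'dihedrals.R'
    'pca.R'
    'cluster.R'
    'convergence.R'
    'structure.R'
    'io.R'
    'pipeline.R'
    'plots.R'
    'sampler.R'
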