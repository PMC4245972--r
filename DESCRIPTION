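Package: ebase
Title: Nucleobase-Centric Analysis of RNA Three-Dimensional Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Represents RNA (and DNA) three-dimensional structures as one
    oriented bead per nucleobase and builds the analyses that follow from
    that representation: annotation of base-pairing and base-stacking
    contacts inside an ellipsoidal interaction shell, a knowledge-based
    scoring function for ranking structural decoys based on Gaussian kernel
    density estimation of relative base positions, interaction-network-aware
    structure deviation metrics alongside classical baselines (RMSD, dRMSD,
    interaction network fidelity), coefficient-of-variation analysis of
    trajectories, and sliding-window search for three-dimensional structural
    motifs. Includes generators for ideal A-form duplexes, register-shifted
    duplexes, noise decoys and toy trajectories so that all analyses can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'rna-io.R'
    'geometry.R'
    'scoring.R'
    'deviation.R'
    'motif.R'
    'fixtures.R'
    'cli.R'
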