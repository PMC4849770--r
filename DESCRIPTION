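Package: phladyn
Title: Comparative Dynamics of Peptide-HLA and Peptide-HLA-TCR Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trajectory analysis for comparing conformational ensembles of
    peptide-MHC (p-HLA) and peptide-MHC-T-cell-receptor complexes.
    Implements rigid-body (Kabsch) superposition, radius-of-gyration and
    principal-inertia-axis geometry, RMSD/RMSF fluctuation statistics with
    significance testing, salt-bridge detection with time-averaged
    inverse-distance adjacency matrices compared through normalized Frobenius
    distances, quasi-harmonic conformational entropy from mass-weighted
    covariance matrices with the associated binding thermodynamic cycle, and
    a synthetic harmonic-ensemble generator with closed-form oracles so every
    stage can be validated without molecular-dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
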