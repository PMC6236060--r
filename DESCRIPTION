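Package: cpmgdisp
Title: Two-Site Exchange Analysis of 15N CPMG Relaxation Dispersion Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for backbone amide 15N Carr-Purcell-Meiboom-Gill
    (CPMG) relaxation dispersion experiments on proteins undergoing
    microsecond-to-millisecond two-site conformational exchange. Provides the
    closed-form Carver-Richards model and a numerical Bloch-McConnell
    propagation oracle, conversion of constant-time peak intensities to
    effective transverse relaxation rates, per-residue screening and
    classification, global fitting of exchange rate constants and state
    populations shared across residues and static fields, synthetic
    multi-state dataset generation for validation, set-level comparison of
    exchanging residues across ligand states and against chemical-shift
    covariance (CHESCA) cluster lists, and residue interaction-network
    mapping over protein coordinates with typed contacts and path tracing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    bio3d,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
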