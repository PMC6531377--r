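Package: gpcrdyn
Title: Conformational-State Analysis of GPCR Molecular Dynamics Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing conformational states of G protein-coupled
    receptors from multi-run molecular dynamics ensembles: torsion-angle
    extraction with first-order Gibbs entropy and undersampling correction,
    pairwise mutual information of torsional distributions, allosteric
    communication pathways and pipelines on mutual-information-weighted
    residue graphs, ligand-receptor contact occupancy and sustained-contact
    classification, per-atom flexibility (RMSF/B-factor), ligand spatial
    distribution functions, grid-based binding-site volume, activation-state
    projection maps, and a Bennett Acceptance Ratio free-energy estimator
    for forward/reverse work samples. Includes synthetic trajectory and
    work-sample generators with closed-form ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
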