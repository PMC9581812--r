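Package: cookesim
Title: Implicit-Solvent Coarse-Grained Simulation of Peptide/Lipid
    Self-Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for implicit-solvent
    coarse-grained self-assembly of lipids and amphipathic peptides. Provides
    the Cooke 3-bead lipid model and a 42-bead hexagonal-stack peptide with
    elastic-network rigidity, Langevin NVT dynamics with cell-list neighbor
    search and a ramped-timestep equilibration protocol, random system
    construction at target composition and concentration, and a complete
    aggregate-analysis pipeline: hydrophobic-bead clustering, micelle/disc
    classification by radius of gyration, principal-component size metrics,
    critical micelle concentration estimation, a replica ergodic measure, and
    finite-size phase diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    graphics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
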