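Package: lassotop
Title: Non-Covalent Lasso Entanglement Detection and Misfolding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects non-covalent lasso entanglements (NCLEs) in protein
    structures from the discrete Gauss linking integral, clusters degenerate
    entanglements into non-redundant representatives, tracks entanglement
    changes along simulation trajectories through the order parameters Q, G
    and K, builds Q-G Markov state models with metastable lumping, folding
    pathways and Jensen-Shannon divergence between conditions, tests
    simulated ensembles for consistency with limited-proteolysis and
    crosslinking mass-spectrometry signals via permutation tests with FDR
    control, and runs proteome-scale misfolding-association statistics with
    Metropolis Monte Carlo candidate selection. Ships seed-deterministic
    synthetic generators (parametric lasso curves with known linking numbers,
    toy trajectories with planted entanglement gains and mirrors, peptide
    abundance tables, and Bernoulli residue tables) so the whole stack is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
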