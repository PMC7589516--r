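Package: t6duel
Title: Agent-Based Simulation of Bacterial Type VI Secretion System Duels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates contact-dependent warfare between rod-shaped bacteria
    growing on a surface patch. Cells are rigid spherocylinders that grow
    exponentially on a finite resource quota, divide with noise, are relaxed
    to mechanical quasi-equilibrium by a regularized impulse solver, and can
    stab neighbours with toxin-laden type VI secretion system (T6SS) needles.
    Firing strategies include constitutive random firing, unarmed, cheater,
    and aimed tit-for-tat retaliators of arbitrary multiplicity. An
    adaptive-dynamics layer turns competition outcomes into invasion-fitness
    tables, local and global invasion indices (including mutual-immunity,
    cheater and within-patch relatedness weightings), pairwise invasibility
    plots and evolutionarily stable firing-rate estimates, together with the
    static hit-probability assay and comparative statistics used to dissect
    why strong, aimed retaliation beats random firing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
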