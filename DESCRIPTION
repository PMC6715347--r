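Package: gamsig
Title: Ligand-Receptor Signaling and the Evolution of Mating Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Individual-based simulation of gamete signaling and the
    evolution of self-incompatible mating types in isogamous populations.
    Surface-bound ligand and receptor dynamics within each cell are solved
    at steady state from mass-action kinetics; the quality of the pairwise
    signaling interaction between two cells determines their mating
    probability, which drives selection in a finite haploid population with
    recurrent quantitative mutation of the production rates, recombination
    between the ligand and receptor loci, and an evolving recombination
    modifier. Includes deterministic invasion-fitness analysis, scenario
    drivers for equilibrium, invasion, recombination-sweep and
    linkage-coevolution experiments, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
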