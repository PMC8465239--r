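Package: dpdlipid
Title: Dissipative Particle Dynamics of Asymmetric Lipid Membranes under Shear
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coarse-grained dissipative particle dynamics (DPD) simulator for
    two-species asymmetric lipid systems in explicit water, with reverse
    non-equilibrium (momentum-swap) shear, and the standard observables used to
    characterise amphiphile self-assembly: species density profiles, the P2
    nematic order parameter of head groups, per-chain gyration tensors and the
    shape factor, Irving-Kirkwood pressure and interfacial-tension profiles,
    plus a percolation-based classifier that maps final configurations onto
    membrane, tube and vesicle phases. The pair-force kernel, bonded forces,
    cell-list neighbour search and the modified velocity-Verlet integrator are
    implemented in C++; all analysis functions take and return tidy data
    frames.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
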