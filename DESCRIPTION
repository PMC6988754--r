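Package: excitonring
Title: Frenkel Exciton Models of LH2 Antenna Rings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the excitonic structure of nonameric LH2
    light-harvesting antenna complexes. Generates ideal and disordered
    C9-symmetric double-ring pigment ensembles (an 18-site B850-like ring
    plus a 9-site B800-like ring), computes geometric descriptors
    (macrocycle centers, orientation factors, dihedrals, hydrogen-bond
    distances), evaluates excitonic couplings by the point-dipole and
    transition-charge routes with an induced-point-dipole
    polarizable-environment screening term, assembles Frenkel Hamiltonians
    with an optional charge-transfer manifold, performs symmetry averaging,
    ring quantum-number assignment and exciton-width analysis, synthesizes
    Lorentzian absorption spectra, and runs site-energy correction and
    coupling-scaling experiments. Includes a statistical layer for
    bond-length regressions of site energies, class-wise coupling
    statistics and a classical per-residue environment contribution ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
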