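Package: tslocate
Title: Double-Ended Transition-State Location and Catalytic-Cycle Energetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Engine-agnostic toolkit for locating first-order saddle points
    (transition states) on molecular potential energy surfaces by a
    double-ended biased-pair ascent, partitioned saddle refinement, subset
    mass-weighted vibrational validation, and intrinsic-reaction-coordinate
    following.  Includes analytic test surfaces and a toy proton-transfer
    potential, XYZ/PDB structure I/O, covalent-topology diffing and
    neutralization mutations, and thermodynamic-cycle bookkeeping of heats
    of formation (electrostatic interaction cycles, hydrogen-bond energy
    changes, mutation double differences, and residue charge audits) for
    enzyme catalytic cycles such as the serine protease chymotrypsin.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
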