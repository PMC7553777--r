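Package: repswap
Title: Repeat-Swap Modeling and Elevator-Motion Analysis for
    Inverted-Topology Membrane Transporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the conformational analysis of elevator-type
    secondary transporters with internal inverted-repeat topology.
    Generates approximate opposite-state target models by the
    repeat-swap construction (180-degree rotation about a
    membrane-parallel axis followed by repeat-permuted rigid-body
    alignment), quantifies transport-domain elevator motion (rotation,
    membrane-normal translation, domain RMSDs), evaluates spin-angle
    and membrane-normal-distance collective variables, emits biased-MD
    restraint configurations in the Colvars dialect, analyses
    inter-helix hinge and elbow angles and binding-site RMSD time
    series, and computes the per-residue C-alpha to carbonyl-carbon
    bond-length model-quality statistic.  A synthetic helical-bundle
    generator with recorded ground truth makes every stage testable
    without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
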