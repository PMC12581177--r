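Package: BetaTwist
Title: Torsional Interconversion Analysis of Amyloid Beta-Sheet Double Layers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying flat-to-twisted conformational interconversion in
    stacked beta-sheet peptide dimers such as the amyloid-beta(20-34) double layer.
    Provides an ideal beta-strand and parallel in-register dimer builder, backbone
    phi/psi torsion kinematics with rigid-segment rotation, geometric hydrogen-bond
    detection and broken-bond accounting, a coarse surrogate energy (steric 12-6 term,
    hydrogen-bond well, harmonic covalent restraints), local minimization, and a
    nudged-elastic-band minimum-energy-path relaxer with activation-barrier and
    steric-contact reporting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, bio3d, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
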