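Package: hairpintools
Title: Conformational Analysis of Beta-Hairpin Peptide Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometric conformational analysis for beta-hairpin peptide
    conformer ensembles, including peptides with backbone N-amination
    (hydrazino acids). Provides an internal-to-Cartesian peptide chain
    builder, hydrogen-bond population analysis under medium-strong and
    weak geometric criteria (including intraresidue C6 and NH2(i)-CO(i-2)
    bonds of N-aminated residues), beta-turn type I'/II' classification
    and peptide-plane-flip counting, a cross-strand hairpin twist metric,
    Ramachandran-region occupancies, conformational clustering by the
    Daura algorithm over backbone RMSD, NOE back-calculation with
    r^-6 ensemble averaging and pseudoatom corrections, and a synthetic
    Markov-state conformer-ensemble generator with planted occupancies
    for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
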