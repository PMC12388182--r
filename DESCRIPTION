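Package: zobmol
Title: Zero-Order-Bond Molecular Graphs with HOSE-Code NMR Shift Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cheminformatics toolkit in which organic, organometallic and
    coordination compounds share a single graph representation based on
    zero-order bonds and explicit per-atom hydrogen counts. On top of that
    representation it provides extended V2000 molfile/SDF input and output,
    implicit-hydrogen and aromaticity rules that tolerate metals, canonical
    atom ranking with a structure-identity key, SMILES output extended with a
    zero-bond symbol, extended HOSE-code generation, HOSE-based 13C/1H
    chemical-shift prediction with sphere fallback and reliability warnings,
    and two-stage substructure search (path-fingerprint screening followed by
    exact zero-bond-aware subgraph matching). Includes generators for
    synthetic metallocene families and shift databases used in the tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
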