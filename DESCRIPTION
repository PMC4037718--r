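Package: flspace
Title: Fragrance Chemical Space Analysis with Molecular Quantum Numbers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the chemical space of fragrance molecules.
    Computes the 42 Molecular Quantum Number (MQN) integer descriptors on
    molecules ionized at pH 7.4, applies the fragrance-likeness filter
    (heavy atom count <= 21, elements C/H/O/S, O+S <= 3, at most one
    hydrogen-bond donor), performs exact city-block-distance similarity
    searches over an MQN-sum hashed index with database bit masks, builds
    PCA-based colour-coded chemical-space maps, and runs ligand-based
    virtual-screening enrichment studies (ROC/AUC, recovery at database
    fractions) in MQN, substructure-fingerprint, extended-connectivity-
    fingerprint and molecular-weight descriptor spaces. Molecule parsing,
    canonicalization and fingerprints are delegated to Open Babel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    jsonlite,
    png,
    optparse,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Open Babel (obabel on the PATH, used for fingerprints)
Config/testthat/edition: 3
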