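Package: cryptosite
Title: Mining Cryptic Phosphosites in Predicted Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies "cryptic" phosphosites: phosphorylated serines,
    threonines and tyrosines whose side chains are buried in the native
    protein core and therefore accessible to kinases only in partially
    folded states. Provides Shrake-Rupley solvent-accessible surface area
    and relative solvent accessibility (RSA) on AlphaFold-style models
    (pLDDT in the B-factor column); a dynamical filter that decomposes
    structures into quasi-rigid domains via beta-Gaussian elastic-network
    normal modes and spectral clustering and scores each site by its
    proportion of intra-domain contacts; alignment-column entropic
    conservation scores; cancer-mutation cross-referencing with
    phosphomimetic classification; and a coarse-grained ratchet-and-pawl
    biased folding simulator with a bias-functional trajectory score.
    Seeded generators produce every synthetic input with known ground
    truth.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
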