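Package: hyscav
Title: Ancestral Reconstruction and Gas-Cavity Evolution in Selenoprotein Hydrogenases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An in-silico resurrection toolkit for studying how gas cavities
    evolve in selenocysteine-containing [NiFeSe] hydrogenases. Provides
    GTR+Gamma(+I) pruning likelihood and marginal ancestral sequence
    reconstruction on a fixed rooted tree, Nei-Gojobori (NG86) codon-based
    selection profiling (per-column deltaN/deltaS with a codon-based Z-test),
    opal-codon (UGA -> Sec) readthrough translation with a SECIS-like
    stem-loop scanner, alpha-complex detection and classification of surface
    pockets and sealed internal cavities from atomic coordinates, cavity
    lineage tracking across a phylogeny, and an overlay of cavity-forming
    positions with the selection profile. A seeded synthetic-data module
    generates trees, codon alignments with planted selection regimes, and
    atom-cloud structures with voids of known geometry so every stage is
    verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    bio3d,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
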