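Package: fragtree
Title: Fragmentation-Tree Annotation of Small Molecules from Low-Resolution Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structural annotation of small molecules from centroided MS2/MSn
    peak lists acquired on low-resolution (unit-mass) instruments such as
    miniaturized ion traps. Builds maximum-weight fragmentation trees from
    spectra via exhaustive molecular-formula enumeration under element bounds,
    simulates collision-induced fragmentation of candidate structures with a
    configurable registry of cleavage and rearrangement rules (C-C/C-O/C-N
    heterolysis, neutral losses, McLafferty and retro-Diels-Alder
    rearrangements, flavonoid- and stilbene-specific rules) to produce SMILES
    trees, ranks candidates by an explicit tree-alignment similarity score
    normalized by the perfect-match score, and annotates each fragment peak
    with a substructure and neutral loss. Includes a compact spectrum-to-SMILES
    encoder-decoder sequence model with fragment-seeded re-prediction and a
    synthetic-data module that forward-simulates spectra for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
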