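Package: mdartools
Title: Sequence-Based Classification of Plant Monodehydroascorbate Reductase Isoforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for assigning plant monodehydroascorbate
    reductase (MDAR) protein sequences to three subcellular-targeting classes
    (chloroplastic/mitochondrial, peroxisomal-membrane, cytosolic/peroxisomal)
    from targeting-signal features: C-terminal PTS1-like tripeptides,
    transmembrane spans with adjacent basic clusters (mPTS), N-terminal
    organellar extensions, and conserved catalytic residues. Includes an
    in-package neighbor-joining phylogeny with bootstrap supports for clade
    corroboration, Mendelian segregation calculations with lethal genotype
    classes, spectrophotometric enzyme-assay arithmetic, and a synthetic
    MDAR-family generator with planted signals and truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
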