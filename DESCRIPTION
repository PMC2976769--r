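Package: ghMotif
Title: Signature Motifs and Structural Analysis of the Lysozyme Glycoside
    Hydrolase Superfamily
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing structurally related glycoside hydrolase
    (GH) families of the lysozyme superfamily. Transforms matrices of
    pairwise structural-similarity Z-scores into distances, builds UPGMA
    clustering trees with leave-one-out (Lanyon jackknife) node-reliability
    assessment, derives entropy-based per-column conservation profiles from
    family alignments, extracts beta-hairpin signature motifs, builds
    position-specific log-odds profiles and evaluates their search
    sensitivity and specificity, and characterises active-site geometry
    (backbone torsions, beta-turn and hairpin classification, catalytic
    residue distance tables). Includes generators for synthetic alignments,
    similarity matrices and peptide coordinates so that every stage of the
    pipeline can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Clustering, MultipleSequenceAlignment, StructuralPrediction,
    SequenceMatching, Software
RoxygenNote: 7.3.3
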