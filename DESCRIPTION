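Package: subspec
Title: Subfamily-Specific Residue Conservation and Structural Roles in Domain Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies residues selectively conserved in subfamilies of a
    protein domain family defined by distinct domain architectures, and assigns
    those residues structural and functional roles from 3D structures. Provides
    domain-architecture filtering of homologue sets with boundary-relaxation
    rules and greedy redundancy removal at a sequence-identity cutoff; alignment
    column classification into shared-conserved, subfamily-specific and
    nonspecific positions with a buried-residue exclusion; Shrake-Rupley
    solvent-accessible surface area and relative accessibility; typed contact
    detection (hydrogen bonds, salt bridges, hydrophobic contacts, water
    bridges, ligand polar contacts) with segment/chain context labels; and
    per-residue role records distinguishing direct interface residues from
    second-shell residues that maintain them, including conformer comparisons.
    A synthetic-data generator produces ground-truth-labelled alignment pairs,
    domain-annotation tables and toy coordinate files so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
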