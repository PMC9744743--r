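Package: hsgraft
Title: Detection and Grafting of Heparan Sulfate Binding Sites on Protein
    Structures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies heparan sulfate (HS) binding sites on protein
    structures and proposes single point mutations that introduce or remove
    them. Detects linear HS-binding motifs (patterns of basic residues such
    as XBBXBX) in the amino-acid sequence and spatial HS-binding clusters
    (surface-exposed basic residues whose charged groups fall within
    characteristic 5-10 or ~20 Angstrom distance bands) on the structure.
    Candidate mutations are screened against solvent exposure, side-chain
    orientation, masked regions (e.g. antibody variable domains) and
    hydrophobicity constraints, ranked, and verified by re-scanning the
    mutant. Includes a deterministic Shrake-Rupley solvent-accessible
    surface area engine, Henderson-Hasselbalch net-charge accounting, and a
    synthetic-structure fixture generator with planted binding-site
    geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
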