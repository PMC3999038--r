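Package: peroxscan
Title: Detection and Classification of Expressed Fungal Secretory
    Peroxidase Transcripts from Degenerate-Primer Amplicon Pools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for surveying expressed fungal secretory peroxidases
    (class II peroxidases, unspecific peroxygenases, dye-decolorizing
    peroxidases) in environmental cDNA. Implements in-silico PCR with
    IUPAC degenerate primers (including inosine), ambiguity-aware
    translation, catalytic-residue classification against anchor
    references (Trp-171/Asp-175 for class II subtypes, the
    Arg-329/Leu-354/Phe-356 peroxide pocket for DyPs, length grouping
    for UPOs), Poisson-corrected neighbor-joining phylogenetics with
    bootstrap clade support, amplicon dereplication and richness
    reporting, litter peroxidase-activity unit conversion, and a fully
    seeded synthetic amplicon-pool generator with per-record ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
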