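Package: rgcontext
Title: Sequence-Context Analysis of Arginine/Glycine-Rich (RG) Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection and sequence-context profiling of arginine/glycine-rich
    (RG/RGG, "GAR") motifs in protein sequences. Scans proteomes for RG motifs
    built from RGG triplets and RG duplets, filters them against intrinsically
    disordered region (IDR) annotations, partitions proteins into motif / mIDR /
    oIDR / structured regions, classifies motif proteins into functional
    ("phase-separating and nucleic-acid-binding") and non-functional study sets,
    and compares the sets by amino-acid composition, physicochemical block
    properties (NCPR, aromaticity, hydropathy, disorder-promoting fraction),
    IDR-constrained sliding-window profiles, motif-domain distances, aromatic
    subset GO enrichment and PTM enrichment with mIDR-length normalization.
    Includes a synthetic-proteome generator with planted ground truth so the
    whole pipeline can be exercised and validated end to end without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
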