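Package: scafmend
Title: Contiguity Repair of Bionano Hybrid Scaffolds
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes the file bundle produced by a Bionano Genomics
    hybrid-scaffolding run (key, CMAP, XMAP) together with the draft assembly
    to remove artificially duplicated contig junctions. Adjacent contigs that
    share enzymatic label sites on the anchor map are fused at the shared
    label; junctions without shared labels are re-sized from optical-map
    coordinates and, when the estimated gap is small, rescued by local
    sequence alignment of the contig ends; small contigs whose alignment span
    is contained in another contig are re-inserted at their original place.
    Emits a more contiguous scaffold FASTA and an AGP v2.1 file describing
    the new organization, plus a per-junction decision report. Includes a
    synthetic-fixture simulator (fragmented genome, in-silico labelling,
    anchor and alignment files with known ground truth) and assembly
    contiguity metrics (NX/LX, auN).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
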