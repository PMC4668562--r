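Package: ltrscape
Title: Structural Annotation and Comparative Evolution of LTR Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide detection and classification of long terminal repeat
    (LTR) retrotransposons from assembled genomes: structural discovery of
    intact elements via direct-repeat search with target-site-duplication
    (TSD) detection, homology recovery of solo LTRs, family clustering and
    Copia/Gypsy/TRIM/LARD superfamily assignment, insertion-age dating from
    LTR-LTR divergence (T = K/2r), window-based randomization tests of
    chromosomal distribution, Marey-map recombination rates, junction-based
    calling of orthologous insertions between two related genomes, NG86
    Ka/Ks estimation on ortholog coding sequences, and neighbor-joining
    lineage trees of family reverse-transcriptase consensi. Includes a
    synthetic-genome simulator that plants elements with known divergence
    and orthology so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    data.table,
    ape,
    rtracklayer,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
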