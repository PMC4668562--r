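# Neighbor-joining trees of family consensus RT regions and
# nearest-reference lineage assignment.

#' Pairwise Jukes-Cantor distance matrix from global alignments
#'
#' Each pair is globally aligned; gap and N columns are excluded and the
#' mismatch proportion is JC-corrected. Saturated pairs (p >= 0.75) are
#' set to a documented cap of 3.0 and flagged via the `"saturated"`
#' attribute.
#'
#' @param sequences named character vector or `DNAStringSet` (>= 3, each
#'   >= 100 bp).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distances <- function(sequences) {
  nm <- names(sequences)
  seqs <- as.character(sequences)
  n <- length(seqs)
  stopifnot(n >= 3, all(nchar(seqs) >= 100))
  if (is.null(nm)) nm <- paste0("s", seq_len(n))
  mat <- sub_matrix(1, -1)
  D <- matrix(0, n, n, dimnames = list(nm, nm))
  sat <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(seqs[i]),
                                          Biostrings::DNAString(seqs[j]),
                                          type = "global",
                                          substitutionMatrix = mat,
                                          gapOpening = 5, gapExtension = 1)
      pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
      sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
      keep <- pa %in% c("A", "C", "G", "T") & sa %in% c("A", "C", "G", "T")
      p <- mean(pa[keep] != sa[keep])
      if (p >= 0.75) {
        D[i, j] <- D[j, i] <- 3.0
        sat[i, j] <- sat[j, i] <- TRUE
      } else {
        D[i, j] <- D[j, i] <- jc_correct(p)
      }
    }
  }
  attr(D, "saturated") <- sat
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]); negative branch lengths
#' are clamped to zero with the deficit transferred to the sibling branch,
#' preserving path lengths approximately. Optionally rooted on an
#' outgroup taxon.
#'
#' @param D symmetric distance matrix with taxon dimnames.
#' @param outgroup optional taxon name to root the emitted tree on.
#' @return An [ape::phylo] tree with branch lengths.
#' @export
nj_tree <- function(D, outgroup = NULL) {
  if (!isSymmetric(unname(as.matrix(D)), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  if (nrow(as.matrix(D)) < 3) stop("need >= 3 taxa")
  tr <- ape::nj(as.dist(D))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sibs) > 0) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] +
        tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  if (!is.null(outgroup)) tr <- ape::root(tr, outgroup, resolve.root = TRUE)
  tr
}

#' Extract the RT region of a family consensus internal sequence
#'
#' The best-scoring window of the internal consensus against the
#' superfamily RT peptide motif, padded by `pad` bp of context on each
#' side.
#'
#' @param internal_seq consensus internal sequence.
#' @param superfamily `"Copia"` or `"Gypsy"`.
#' @param motifs motif table.
#' @param pad context padding, bp.
#' @return Character RT-region sequence, or `NA` if no motif hit.
#' @export
extract_rt_region <- function(internal_seq, superfamily,
                              motifs = bundled_motifs(), pad = 60) {
  if (is.na(internal_seq)) return(NA_character_)
  pep <- motifs$peptide[motifs$superfamily == superfamily &
                          motifs$domain == "RT"]
  if (length(pep) == 0) return(NA_character_)
  hit <- motif_best_hit(internal_seq, pep)
  if (is.null(hit)) return(NA_character_)
  s <- max(1, hit$nt_start - pad)
  e <- min(nchar(internal_seq), hit$nt_end + pad)
  out <- substr(internal_seq, s, e)
  if (hit$strand == "-") out <- revcomp(out)
  out
}

#' Assign a family to a named lineage by nearest reference RT
#'
#' JC distance from the family RT region to every bundled reference of the
#' same superfamily; the nearest reference's lineage is assigned.
#' Distances above `cap` give `"unassigned"`; exact ties are broken by
#' lexicographic reference id and flagged.
#'
#' @param rt_region family consensus RT nucleotide sequence (or NA).
#' @param superfamily `"Copia"` or `"Gypsy"`.
#' @param refs reference table from [bundled_lineage_refs()].
#' @param cap maximum acceptable distance (default 1.5).
#' @return list `lineage`, `reference`, `distance`, `tie`.
#' @export
assign_lineage <- function(rt_region, superfamily,
                           refs = bundled_lineage_refs(), cap = 1.5) {
  unassigned <- list(lineage = "unassigned", reference = NA_character_,
                     distance = NA_real_, tie = FALSE)
  if (is.na(rt_region) || !superfamily %in% c("Copia", "Gypsy")) {
    return(unassigned)
  }
  rs <- refs[refs$superfamily == superfamily, , drop = FALSE]
  rs <- rs[order(rs$lineage), , drop = FALSE]
  if (nrow(rs) == 0) return(unassigned)
  mat <- sub_matrix(1, -1)
  dist_to <- vapply(rs$seq, function(ref) {
    al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(rt_region),
                                        Biostrings::DNAString(ref),
                                        type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 1)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    keep <- pa %in% c("A", "C", "G", "T") & sa %in% c("A", "C", "G", "T")
    if (sum(keep) < 30) return(3.0)
    p <- mean(pa[keep] != sa[keep])
    if (p >= 0.75) 3.0 else jc_correct(p)
  }, numeric(1))
  best <- min(dist_to)
  if (best > cap) return(unassigned)
  hits <- which(dist_to == best)
  list(lineage = rs$lineage[hits[1]], reference = rs$lineage[hits[1]],
       distance = best, tie = length(hits) > 1)
}

#' Lineage assignment for a whole family table
#'
#' @param families family table from [classify_elements()].
#' @param refs reference table from [bundled_lineage_refs()].
#' @param cap distance cap passed to [assign_lineage()].
#' @return `families` with `lineage` and `lineage_distance` columns.
#' @export
assign_lineages <- function(families, refs = bundled_lineage_refs(),
                            cap = 1.5) {
  res <- lapply(seq_len(nrow(families)), function(i) {
    rt <- extract_rt_region(families$consensus_internal[i],
                            families$superfamily[i])
    assign_lineage(rt, families$superfamily[i], refs, cap)
  })
  families$lineage <- vapply(res, `[[`, "", "lineage")
  families$lineage_distance <- vapply(res, `[[`, 0, "distance")
  families
}
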