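#' Read a genome FASTA into a normalized DNAStringSet
#'
#' Residues are uppercased, `U` is converted to `T`, and any letter outside
#' the `{A,C,G,T,N}` alphabet (IUPAC ambiguity codes included) is replaced by
#' `N`; downstream detection treats `N` as a universal mismatch. The number
#' of replaced residues is reported as a warning.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique names.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) {
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(x))
  seqs <- chartr("U", "T", seqs)
  n_bad <- sum(vapply(seqs, function(s) {
    sum(!strsplit(s, "")[[1]] %in% c("A", "C", "G", "T", "N"))
  }, numeric(1)))
  if (n_bad > 0) {
    warning(n_bad, " non-ACGTN residue(s) replaced by N")
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1))
  }
  out <- Biostrings::DNAStringSet(unname(seqs))
  names(out) <- nm
  out
}

#' Write a genome to FASTA
#'
#' @param genome a [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 80L)
  invisible(path)
}

#' Write interval annotations as GFF3
#'
#' Annotations use the package-wide 1-based inclusive coordinate
#' convention, which is also GFF3's. Columns beyond `seq_id`, `start`,
#' `end`, `strand`, `kind`, `score` become `key=value` attributes and
#' round-trip through [read_gff3()]. Emission goes through
#' [rtracklayer::export()].
#'
#' @param annotations data.frame with at least `seq_id`, `start`, `end`;
#'   optional `strand`, `kind`, `score` and arbitrary attribute columns.
#' @param path output path.
#' @param genome optional [Biostrings::DNAStringSet] used to validate that
#'   intervals lie within sequence bounds (hard error otherwise).
#' @param source source tag for column 2.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotations, path, genome = NULL,
                       source = "ltrscape") {
  an <- as.data.frame(annotations)
  if (nrow(an) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  stopifnot(all(c("seq_id", "start", "end") %in% names(an)))
  if (any(an$start < 1 | an$end < an$start)) {
    stop("invalid interval: start must be >= 1 and <= end")
  }
  if (!is.null(genome)) {
    lens <- setNames(Biostrings::width(genome), names(genome))
    if (any(is.na(lens[an$seq_id])) || any(an$end > lens[an$seq_id])) {
      stop("interval exceeds sequence length")
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = an$seq_id,
    ranges = IRanges::IRanges(an$start, an$end),
    strand = if ("strand" %in% names(an)) {
      ifelse(an$strand %in% c("+", "-"), an$strand, "*")
    } else "*")
  gr$source <- source
  gr$type <- if ("kind" %in% names(an)) an$kind else "region"
  if ("score" %in% names(an)) gr$score <- an$score
  for (k in setdiff(names(an), c("seq_id", "start", "end", "strand",
                                 "kind", "score"))) {
    S4Vectors::mcols(gr)[[k]] <- as.character(an[[k]])
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file into the annotation data.frame convention
#'
#' @param path GFF3 path.
#' @return data.frame with `seq_id`, `start`, `end`, `strand`, `kind` and
#'   one column per attribute key present in the file.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      kind = character()))
  }
  out <- data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    kind = as.character(gr$type),
                    stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  for (k in setdiff(names(mc), c("source", "type", "phase"))) {
    out[[k]] <- if (is.list(mc[[k]])) {
      vapply(mc[[k]], function(v) {
        if (length(v) == 0) NA_character_ else paste(v, collapse = ",")
      }, character(1))
    } else as.character(mc[[k]])
  }
  out
}

#' Read a genetic-map marker table
#'
#' Expects a TSV with header `chrom  bp  cM`. Rows are sorted by
#' (chromosome, physical position); duplicate physical positions on a
#' chromosome are collapsed to their mean genetic position. Chromosomes with
#' fewer than two markers are flagged unusable (attribute `"unusable"`).
#'
#' @param path TSV path.
#' @return data.frame `chrom`, `bp`, `cM`, sorted, with attribute
#'   `unusable` listing chromosomes that cannot support rate estimation.
#' @export
read_marker_map <- function(path) {
  m <- data.table::fread(path, header = TRUE, sep = "\t",
                         col.names = c("chrom", "bp", "cM"))
  if (any(m$bp < 0) || any(m$cM < 0)) stop("negative marker positions")
  m <- m[, list(cM = mean(cM)), by = c("chrom", "bp")]
  data.table::setorderv(m, c("chrom", "bp"))
  out <- as.data.frame(m)
  tab <- table(out$chrom)
  attr(out, "unusable") <- names(tab)[tab < 2]
  out
}
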