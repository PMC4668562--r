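# Family clustering on LTR sequences (single linkage, 80-80-80 rule),
# consensus building, and superfamily assignment from the order of the
# integrase (INT) and reverse-transcriptase (RT) domains in the internal
# region (INT before RT: Copia; RT before INT: Gypsy), with the structural
# TRIM/LARD rules for motif-free families.

# local alignment identity and coverage between two LTR sequences
ltr_pair_link <- function(a, b, identity_threshold, coverage_threshold,
                          min_align) {
  mat <- sub_matrix(1, -1)
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 1)
  alen <- nchar(as.character(Biostrings::alignedPattern(al)))
  if (alen == 0) return(FALSE)
  ident <- Biostrings::nmatch(al) / alen
  shorter <- min(nchar(a), nchar(b))
  ident >= identity_threshold && alen >= coverage_threshold * shorter &&
    alen >= min_align
}

#' Cluster elements into families by LTR homology (single linkage)
#'
#' Two elements are linked when a local alignment of their LTRs reaches
#' >= 80% identity over >= 80% of the shorter LTR and >= 80 aligned bp;
#' connected components are families. Family ids are assigned by
#' decreasing size, ties by leftmost member, and are invariant to input
#' order.
#'
#' @param elements element table with `ltr5_seq` (see
#'   [element_sequences()]).
#' @param identity_threshold,coverage_threshold,min_align linkage rule.
#' @return `elements` with a `family_id` column.
#' @export
cluster_families <- function(elements, identity_threshold = 0.80,
                             coverage_threshold = 0.80, min_align = 80) {
  n <- nrow(elements)
  if (n == 0) { elements$family_id <- character(0); return(elements) }
  seqs <- elements$ltr5_seq
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  # cheap k-mer prefilter so only plausibly related pairs are aligned
  k <- 12L
  kms <- lapply(seqs, function(s) unique(kmer_ends(dna_codes(s), k)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (find(i) == find(j)) next
      shared <- length(intersect(kms[[i]], kms[[j]]))
      if (shared < 3) next
      if (ltr_pair_link(seqs[i], seqs[j], identity_threshold,
                        coverage_threshold, min_align)) {
        parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  # order families by decreasing size, then leftmost member position
  key <- data.frame(comp = unique(comp))
  key$size <- vapply(key$comp, function(cp) sum(comp == cp), 0L)
  key$left <- vapply(key$comp, function(cp) {
    min(elements$start[comp == cp])
  }, 0)
  key <- key[order(-key$size, key$left), ]
  key$family_id <- sprintf("F%03d", seq_len(nrow(key)))
  elements$family_id <- key$family_id[match(comp, key$comp)]
  elements
}

#' Majority-rule consensus of a set of sequences
#'
#' Star alignment of every member to the longest member; column-wise
#' majority with alphabetical tie-breaking; positions whose majority is a
#' gap are dropped.
#'
#' @param seqs character vector of member sequences (>= 1).
#' @return Consensus string.
#' @export
build_consensus <- function(seqs) {
  seqs <- seqs[!is.na(seqs)]
  stopifnot(length(seqs) >= 1)
  if (length(seqs) == 1) return(seqs)
  ref <- seqs[which.max(nchar(seqs))]
  mat <- sub_matrix(1, -1)
  prof <- matrix("-", nrow = length(seqs), ncol = nchar(ref))
  for (i in seq_along(seqs)) {
    if (seqs[i] == ref) {
      prof[i, ] <- strsplit(ref, "")[[1]]
      next
    }
    al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(seqs[i]),
                                        Biostrings::DNAString(ref),
                                        type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 1)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    rp <- 0L
    for (cidx in seq_along(sa)) {
      if (sa[cidx] != "-") {
        rp <- rp + 1L
        prof[i, rp] <- pa[cidx]
      }
    }
  }
  cons <- apply(prof, 2, function(col) {
    tab <- table(factor(col, levels = c("A", "C", "G", "T", "N", "-")))
    names(tab)[which.max(tab)]  # which.max takes the first (alphabetical) max
  })
  paste(cons[cons != "-"], collapse = "")
}

# --- domain-motif machinery -------------------------------------------------

blosum62 <- function() {
  if (is.null(.mat_cache[["BLOSUM62"]])) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .mat_cache[["BLOSUM62"]] <- e$BLOSUM62
  }
  .mat_cache[["BLOSUM62"]]
}

# best local-alignment hit of a peptide motif in the six-frame translation
# of a nucleotide sequence; returns NULL or nt-coordinates of the hit
motif_best_hit <- function(nt, peptide, min_score_frac = 0.40) {
  b62 <- blosum62()
  pep <- Biostrings::AAString(peptide)
  self <- Biostrings::pairwiseAlignment(pep, pep, type = "local",
                                        substitutionMatrix = b62,
                                        gapOpening = 100, gapExtension = 10)
  self_score <- Biostrings::score(self)
  x <- Biostrings::DNAString(gsub("[^ACGT]", "A", toupper(nt)))
  best <- NULL
  for (strand in c("+", "-")) {
    xs <- if (strand == "+") x else Biostrings::reverseComplement(x)
    for (fr in 0:2) {
      if (length(xs) - fr < 3) next
      aa <- Biostrings::translate(Biostrings::subseq(
        xs, fr + 1, fr + 3 * ((length(xs) - fr) %/% 3)),
        if.fuzzy.codon = "X", no.init.codon = TRUE)
      aa <- Biostrings::AAString(chartr("*", "X", as.character(aa)))
      if (length(aa) < 5) next
      al <- Biostrings::pairwiseAlignment(pep, aa, type = "local",
                                          substitutionMatrix = b62,
                                          gapOpening = 100,
                                          gapExtension = 10)
      sc <- Biostrings::score(al)
      if (sc < min_score_frac * self_score) next
      if (is.null(best) || sc > best$score) {
        aa_start <- Biostrings::start(Biostrings::subject(al))
        aa_end <- Biostrings::end(Biostrings::subject(al))
        nt_start_f <- fr + (aa_start - 1) * 3 + 1
        nt_end_f <- fr + aa_end * 3
        if (strand == "+") {
          nt_start <- nt_start_f; nt_end <- nt_end_f
        } else {
          nt_start <- length(x) - nt_end_f + 1
          nt_end <- length(x) - nt_start_f + 1
        }
        best <- list(score = sc, score_frac = sc / self_score,
                     strand = strand, nt_start = nt_start, nt_end = nt_end)
      }
    }
  }
  best
}

#' Assign a superfamily from domain order and structural rules
#'
#' The consensus internal region is translated in six frames and scored
#' against the bundled INT and RT peptide motifs. If both domains are
#' found, their order decides Copia (INT before RT) versus Gypsy (RT
#' before INT). If neither is found the structural rules apply: internal
#' > 4 kb is LARD; internal < 1 kb with element < 2.5 kb is TRIM;
#' otherwise unknown.
#'
#' @param internal_seq consensus internal-region sequence (or NA for a
#'   solo-only family).
#' @param element_len representative full element length, bp.
#' @param motifs motif table from [bundled_motifs()].
#' @param lard_min_internal,trim_max_internal,trim_max_element structural
#'   thresholds, bp.
#' @return One of `"Copia"`, `"Gypsy"`, `"TRIM"`, `"LARD"`, `"unknown"`.
#' @export
assign_superfamily <- function(internal_seq, element_len,
                               motifs = bundled_motifs(),
                               lard_min_internal = 4000,
                               trim_max_internal = 1000,
                               trim_max_element = 2500) {
  if (is.na(internal_seq) || nchar(internal_seq) == 0) return("unknown")
  hit <- function(domain) {
    hs <- lapply(unique(motifs$superfamily), function(sf) {
      pep <- motifs$peptide[motifs$superfamily == sf &
                              motifs$domain == domain]
      if (length(pep) == 0) return(NULL)
      motif_best_hit(internal_seq, pep)
    })
    hs <- hs[!vapply(hs, is.null, logical(1))]
    if (length(hs) == 0) return(NULL)
    hs[[which.max(vapply(hs, `[[`, 0, "score_frac"))]]
  }
  int_hit <- hit("INT")
  rt_hit <- hit("RT")
  if (!is.null(int_hit) && !is.null(rt_hit)) {
    flipped <- int_hit$strand == "-" && rt_hit$strand == "-"
    int_first <- int_hit$nt_start < rt_hit$nt_start
    if (flipped) int_first <- !int_first
    return(if (int_first) "Copia" else "Gypsy")
  }
  ilen <- nchar(internal_seq)
  if (ilen > lard_min_internal) return("LARD")
  if (ilen < trim_max_internal && element_len < trim_max_element) {
    return("TRIM")
  }
  "unknown"
}

#' Family-level classification of an annotated element table
#'
#' Clusters elements into families, builds per-family LTR and internal
#' consensi, assigns superfamilies (solo-only families inherit from the
#' family's intact members, or are classified structurally when possible),
#' and writes the results back onto the element table.
#'
#' @param elements element table (with sequences; see
#'   [element_sequences()]).
#' @param genome the genome, used to extract internal regions.
#' @param ... passed to [cluster_families()].
#' @return list `elements` (with `family_id`, `superfamily`) and
#'   `families` (one row per family: id, size, superfamily, consensus
#'   sequences).
#' @export
classify_elements <- function(elements, genome, ...) {
  if (!"ltr5_seq" %in% names(elements)) {
    elements <- element_sequences(elements, genome)
  }
  elements <- cluster_families(elements, ...)
  seqs <- as.character(genome)
  fams <- lapply(unique(elements$family_id), function(fid) {
    rows <- elements[elements$family_id == fid, , drop = FALSE]
    cons_ltr <- build_consensus(rows$ltr5_seq)
    with_int <- rows[!is.na(rows$internal_start), , drop = FALSE]
    cons_int <- NA_character_
    elem_len <- max(rows$end - rows$start + 1)
    if (nrow(with_int) > 0) {
      ints <- vapply(seq_len(nrow(with_int)), function(i) {
        substr(seqs[[with_int$seq_id[i]]], with_int$internal_start[i],
               with_int$internal_end[i])
      }, character(1))
      cons_int <- build_consensus(ints)
      elem_len <- max(with_int$end - with_int$start + 1)
    }
    sf <- assign_superfamily(cons_int, elem_len)
    data.frame(family_id = fid, size = nrow(rows), superfamily = sf,
               consensus_ltr = cons_ltr, consensus_internal = cons_int,
               stringsAsFactors = FALSE)
  })
  fams <- do.call(rbind, fams)
  elements$superfamily <- fams$superfamily[match(elements$family_id,
                                                 fams$family_id)]
  list(elements = elements, families = fams)
}

#' Ratio of solo to intact copies, (ST+SnT)/(IT+InT)
#'
#' The structural ratio used in superfamily and lineage summary tables; a
#' high ratio indicates frequent solo-LTR formation by unequal
#' recombination. Reported to 2 decimals; `"/"` when there are no intact
#' copies.
#'
#' @param IT,ST,InT,SnT category counts.
#' @return Character: formatted ratio or `"/"`.
#' @export
structural_ratio <- function(IT, ST, InT, SnT) {
  denom <- IT + InT
  if (denom == 0) return("/")
  formatC(round((ST + SnT) / denom, 2), format = "f", digits = 2)
}

#' Superfamily summary table (counts, percentages, ratio, mean age)
#'
#' @param elements element table with `category`, `superfamily` and
#'   optionally `age_my`.
#' @param group grouping column (default `"superfamily"`; use
#'   `"lineage"` for a lineage summary).
#' @return data.frame, one row per group plus a Total row: category
#'   counts, column percentages, subtotal, `(ST+SnT)/(IT+InT)` ratio (2
#'   decimals, `"/"` when undefined) and mean age in My (2 decimals).
#' @export
summarize_superfamilies <- function(elements, group = "superfamily") {
  cats <- c("IT", "ST", "InT", "SnT")
  groups <- unique(elements[[group]])
  tot <- vapply(cats, function(ct) sum(elements$category == ct), 0)
  rows <- lapply(groups, function(g) {
    e <- elements[elements[[group]] == g, , drop = FALSE]
    cnt <- vapply(cats, function(ct) sum(e$category == ct), 0)
    age <- if ("age_my" %in% names(e)) {
      round(mean(e$age_my, na.rm = TRUE), 2)
    } else NA_real_
    data.frame(group = g, n_families = length(unique(e$family_id)),
               IT = cnt["IT"], ST = cnt["ST"], InT = cnt["InT"],
               SnT = cnt["SnT"],
               IT_pct = round(100 * cnt["IT"] / max(1, tot["IT"]), 1),
               ST_pct = round(100 * cnt["ST"] / max(1, tot["ST"]), 1),
               subtotal = nrow(e),
               ratio = structural_ratio(cnt["IT"], cnt["ST"], cnt["InT"],
                                        cnt["SnT"]),
               mean_age_my = age, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(group = "Total", n_families =
                        length(unique(elements$family_id)),
                      IT = tot["IT"], ST = tot["ST"], InT = tot["InT"],
                      SnT = tot["SnT"], IT_pct = 100, ST_pct = 100,
                      subtotal = nrow(elements),
                      ratio = structural_ratio(tot["IT"], tot["ST"],
                                               tot["InT"], tot["SnT"]),
                      mean_age_my = if ("age_my" %in% names(elements)) {
                        round(mean(elements$age_my, na.rm = TRUE), 2)
                      } else NA_real_,
                      stringsAsFactors = FALSE)
  out <- rbind(out, total)
  rownames(out) <- NULL
  out
}
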