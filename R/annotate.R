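# Structural discovery of LTR retrotransposons: direct-repeat search by
# exact k-mer seeding on shared diagonals, X-drop extension, TSD detection
# (one mismatch allowed, 6->5->4 bp), merging of multi-LTR "complex" loci,
# and homology recovery of solo LTRs from the library of detected LTRs.

#' Detection parameter set
#'
#' @param min_ltr_len,max_ltr_len accepted LTR length range, bp.
#' @param min_element_len,max_element_len accepted element span range, bp.
#' @param min_ltr_identity minimum identity between the two LTRs of a
#'   candidate (fraction).
#' @param seed_word exact k-mer length used for seeding.
#' @param tsd_len_range TSD lengths tried, most specific first.
#' @param tsd_max_mismatch mismatches tolerated in a TSD comparison at the
#'   nominal boundary, per TSD length; a lone mismatch in a 4-mer is 75%
#'   identity and indistinguishable from chance, so 4-bp TSDs require an
#'   exact duplication.
#' @param seed_gap maximum gap between seeds chained on one diagonal, bp.
#' @param xdrop score drop terminating diagonal extension (match +1,
#'   mismatch -`mismatch_penalty`).
#' @param mismatch_penalty extension mismatch penalty.
#' @param tsd_jitter boundary jitter (bp) searched for an exact TSD when
#'   none is found at the extended boundaries.
#' @param tsd_jitter_manhattan per-TSD-length caps on the total boundary
#'   shift `|d5| + |d3|` accepted in the jittered search; shorter TSDs get
#'   tighter caps to keep chance duplications rare.
#' @param max_complex_spacer longest internal spacer (bp) allowed between
#'   consecutive LTR copies of a complex locus.
#' @param max_n_frac maximum N fraction tolerated in a reported span.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(min_ltr_len = 100, max_ltr_len = 3000,
                             min_element_len = 300, max_element_len = 15000,
                             min_ltr_identity = 0.80, seed_word = 15,
                             tsd_len_range = 6:4,
                             tsd_max_mismatch = c("6" = 1, "5" = 1,
                                                  "4" = 0),
                             seed_gap = 300, xdrop = 8,
                             mismatch_penalty = 2, tsd_jitter = 8,
                             tsd_jitter_manhattan = c("6" = 8, "5" = 4,
                                                      "4" = 2),
                             max_complex_spacer = 3000,
                             max_n_frac = 0.10) {
  stopifnot(min_ltr_len < max_ltr_len, min_element_len < max_element_len,
            min_ltr_identity > 0, min_ltr_identity <= 1)
  structure(as.list(environment()), class = "detection_params")
}

# k-mer code ending at each position (NA where the window has an N)
kmer_ends <- function(codes, k) {
  as.numeric(stats::filter(codes, 4^(0:(k - 1)), method = "convolution",
                           sides = 1))
}

# seed-pair runs on shared diagonals for one chromosome
diagonal_runs <- function(codes, params) {
  k <- params$seed_word
  km <- kmer_ends(codes, k)
  idx <- data.table::data.table(code = km, end = seq_along(km))
  idx <- idx[!is.na(idx$code)]
  cnt <- idx[, list(N = .N), by = "code"]
  keep <- cnt$code[cnt$N >= 2 & cnt$N <= 50]
  idx <- idx[idx$code %in% keep]
  if (nrow(idx) == 0) return(NULL)
  pr <- merge(idx, idx, by = "code", allow.cartesian = TRUE)
  pr <- pr[pr$end.y > pr$end.x]
  pr$d <- pr$end.y - pr$end.x
  pr <- pr[pr$d >= 50 & pr$d <= params$max_element_len]
  if (nrow(pr) == 0) return(NULL)
  dt <- data.table::data.table(d = pr$d, s1 = pr$end.x - k + 1L)
  data.table::setorderv(dt, c("d", "s1"))
  brk <- c(TRUE, diff(dt$d) != 0 | diff(dt$s1) > params$seed_gap)
  dt$grp <- cumsum(brk)
  runs <- dt[, list(d = d[1], lo = min(s1), hi = max(s1) + k - 1L,
                    nseed = .N), by = "grp"]
  as.data.frame(runs)
}

# X-drop extension of a diagonal run; returns refined lo/hi and identity
extend_diagonal <- function(codes, d, lo, hi, params, win = 800L) {
  n <- length(codes)
  pen <- params$mismatch_penalty
  score_at <- function(p) {
    m <- codes[p] == codes[p + d]
    ifelse(is.na(m), -pen, ifelse(m, 1, -pen))
  }
  # leftwards
  tmax <- min(win, lo - 1L)
  if (tmax > 0) {
    p <- (lo - 1L):(lo - tmax)
    sc <- cumsum(score_at(p))
    j <- which.max(sc)
    if (sc[j] > 0) lo <- lo - j
  }
  # rightwards
  tmax <- min(win, n - (hi + d))
  if (tmax > 0) {
    p <- (hi + 1L):(hi + tmax)
    sc <- cumsum(score_at(p))
    j <- which.max(sc)
    if (sc[j] > 0) hi <- hi + j
  }
  m <- codes[lo:hi] == codes[(lo:hi) + d]
  list(lo = lo, hi = hi, identity = mean(ifelse(is.na(m), FALSE, m)))
}

#' Detect a target site duplication at element boundaries
#'
#' Compares the L-mer immediately left of the element with the L-mer
#' immediately right, for L = 6, 5, 4 (first success wins), allowing one
#' mismatch; N counts as a mismatch. If no TSD is found at the given
#' boundaries, a small boundary jitter is searched for an exact duplication
#' and, on success, the element span is snapped to it.
#'
#' @param seq chromosome residue string.
#' @param start,end element span (1-based inclusive, TSDs excluded).
#' @param params [detection_params()].
#' @param jitter_min_len shortest TSD accepted in the jittered (exact)
#'   search; raise to 5 when boundaries are already well anchored, to
#'   suppress chance 4-mer duplications.
#' @return `NULL`, or list `tsd`, `mismatch`, `start`, `end` (possibly
#'   snapped).
#' @export
detect_tsd <- function(seq, start, end, params = detection_params(),
                       jitter_min_len = 4) {
  n <- nchar(seq)
  cmp <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    sum(ca != cb | ca == "N" | cb == "N")
  }
  probe <- function(s, e, L, max_mm) {
    if (s - L < 1 || e + L > n) return(NULL)
    left <- substr(seq, s - L, s - 1L)
    right <- substr(seq, e + 1L, e + L)
    if (cmp(left, right) <= max_mm) {
      return(list(tsd = left, mismatch = cmp(left, right),
                  start = s, end = e))
    }
    NULL
  }
  jr <- params$tsd_jitter
  offs <- expand.grid(d5 = -jr:jr, d3 = -jr:jr)
  offs$man <- abs(offs$d5) + abs(offs$d3)
  offs <- offs[order(offs$man), , drop = FALSE]
  # Longer TSDs take precedence over boundary jitter, so a duplication
  # eroded by a small extension overshoot is not reported as its own 4-bp
  # suffix. Short TSDs are only accepted near the nominal boundary
  # (tsd_jitter_manhattan), keeping the chance-duplication rate down for
  # elements that truly lack a TSD.
  mm_of <- function(L) {
    if (length(params$tsd_max_mismatch) == 1) {
      return(params$tsd_max_mismatch)
    }
    mm <- params$tsd_max_mismatch[as.character(L)]
    if (is.na(mm)) 0L else mm
  }
  for (L in params$tsd_len_range) {
    hit <- probe(start, end, L, mm_of(L))
    if (!is.null(hit)) return(hit)
    if (jr > 0 && L >= jitter_min_len) {
      lim <- params$tsd_jitter_manhattan[as.character(L)]
      lim <- if (is.na(lim)) 2 * jr else lim
      # extension errors usually hit one boundary only, so offsets along
      # one axis are admitted out to the full radius (L >= 5)
      ok <- offs$man > 0 &
        (offs$man <= lim |
           (L >= 5 & pmin(abs(offs$d5), abs(offs$d3)) == 0))
      for (i in which(ok)) {
        hit <- probe(start + offs$d5[i], end + offs$d3[i], L, 0L)
        if (!is.null(hit)) return(hit)
      }
    }
  }
  NULL
}

#' Structural category from LTR count and TSD presence
#'
#' @param n_ltrs number of LTR copies at the locus.
#' @param has_tsd whether a TSD was detected.
#' @return `"IT"`, `"InT"`, `"ST"`, `"SnT"` or `"complex"`.
#' @export
classify_structure <- function(n_ltrs, has_tsd) {
  if (n_ltrs < 1) stop("malformed element: no LTR span")
  if (n_ltrs >= 3) return("complex")
  if (n_ltrs == 2) {
    if (has_tsd) "IT" else "InT"
  } else {
    if (has_tsd) "ST" else "SnT"
  }
}

n_frac <- function(seq, start, end) {
  s <- substr(seq, start, end)
  lengths(regmatches(s, gregexpr("N", s, fixed = TRUE))) / nchar(s)
}

#' Find intact and complex LTR retrotransposon candidates in one genome
#'
#' Direct repeats on the same strand are found by exact k-mer seeding and
#' diagonal X-drop extension. Pairwise candidates sharing LTR copies are
#' grouped; loci with three or more LTR copies under one outer TSD pair are
#' emitted as complex elements, others are decomposed into the best
#' non-overlapping pairs (TSD-validated pairs first, then identity, length,
#' leftmost). Each simple candidate receives a TSD scan and an IT/InT
#' category.
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param params [detection_params()].
#' @return data.frame of element calls (possibly 0 rows).
#' @export
find_intact_candidates <- function(genome, params = detection_params()) {
  res <- lapply(seq_along(genome), function(j) {
    chrom_intact_calls(names(genome)[j], as.character(genome[[j]]), params)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) empty_elements() else out
}

empty_elements <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             strand = character(), category = character(),
             n_ltrs = integer(), ltr5_start = integer(),
             ltr5_end = integer(), ltr3_start = integer(),
             ltr3_end = integer(), internal_start = integer(),
             internal_end = integer(), tsd = character(),
             identity = numeric(), stringsAsFactors = FALSE)
}

chrom_intact_calls <- function(seq_id, seq, params) {
  codes <- dna_codes(seq)
  runs <- diagonal_runs(codes, params)
  if (is.null(runs) || nrow(runs) == 0) return(NULL)

  # extend each run and filter to plausible LTR pairs
  cands <- lapply(seq_len(nrow(runs)), function(i) {
    e <- extend_diagonal(codes, runs$d[i], runs$lo[i], runs$hi[i], params)
    len <- e$hi - e$lo + 1L
    d <- runs$d[i]
    if (len < params$min_ltr_len || len > params$max_ltr_len) return(NULL)
    if (e$identity < params$min_ltr_identity) return(NULL)
    if (d <= len) return(NULL)  # LTR copies must not overlap
    span <- d + len
    if (span < params$min_element_len || span > params$max_element_len) {
      return(NULL)
    }
    data.frame(a5 = e$lo, b5 = e$hi, a3 = e$lo + d, b3 = e$hi + d,
               identity = e$identity)
  })
  cands <- do.call(rbind, cands)
  if (is.null(cands) || nrow(cands) == 0) return(NULL)

  # deduplicate near-identical candidates (same copy spans)
  cands <- cands[order(-cands$identity), , drop = FALSE]
  sig <- paste(round(cands$a5 / 20), round(cands$b5 / 20),
               round(cands$a3 / 20), round(cands$b3 / 20))
  cands <- cands[!duplicated(sig), , drop = FALSE]

  # cluster LTR copies shared between candidates
  copies <- rbind(data.frame(s = cands$a5, e = cands$b5),
                  data.frame(s = cands$a3, e = cands$b3))
  ord <- order(copies$s)
  cl_id <- integer(nrow(copies))
  cur <- 0L; last_e <- -1L
  for (i in ord) {
    ov <- min(copies$e[i], last_e) - copies$s[i] + 1L
    if (cur == 0L || ov < 0.5 * (copies$e[i] - copies$s[i] + 1L)) {
      cur <- cur + 1L
      last_e <- copies$e[i]
    } else last_e <- max(last_e, copies$e[i])
    cl_id[i] <- cur
  }
  nc <- nrow(cands)
  c5 <- cl_id[seq_len(nc)]; c3 <- cl_id[nc + seq_len(nc)]

  # connected components over copy clusters
  parent <- seq_len(max(cl_id))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nc)) {
    ra <- find(c5[i]); rb <- find(c3[i])
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(seq_along(parent), find, 0L)
  cl_span <- do.call(rbind, lapply(seq_len(max(cl_id)), function(ci) {
    rows <- which(cl_id == ci)
    data.frame(cl = ci, s = min(copies$s[rows]), e = max(copies$e[rows]))
  }))

  calls <- list()
  for (cp in unique(comp)) {
    cls <- which(comp == cp)
    in_comp <- which(c5 %in% cls | c3 %in% cls)
    if (length(cls) >= 3) {
      # candidate complex locus: all copies under one outer TSD pair, with
      # spacers short enough to be internal segments rather than the
      # genomic gap between two independent insertions
      spans <- cl_span[cl_span$cl %in% cls, ]
      spans <- spans[order(spans$s), ]
      lo <- min(spans$s); hi <- max(spans$e)
      gaps <- spans$s[-1] - spans$e[-nrow(spans)] - 1L
      tsd <- if (all(gaps <= params$max_complex_spacer)) {
        detect_tsd(seq, lo, hi, params)
      } else NULL
      if (!is.null(tsd) &&
          (hi - lo + 1L) <= params$max_element_len) {
        calls <- c(calls, list(data.frame(
          seq_id = seq_id, start = tsd$start, end = tsd$end, strand = "+",
          category = "complex", n_ltrs = length(cls),
          ltr5_start = spans$s[1], ltr5_end = spans$e[1],
          ltr3_start = spans$s[nrow(spans)], ltr3_end = spans$e[nrow(spans)],
          internal_start = spans$e[1] + 1L,
          internal_end = spans$s[nrow(spans)] - 1L,
          tsd = tsd$tsd, identity = max(cands$identity[in_comp]),
          stringsAsFactors = FALSE)))
        next
      }
    }
    # decompose into non-overlapping pairwise candidates: prefer pairs
    # whose own boundaries carry a TSD, then identity, length, leftmost
    sub <- cands[in_comp, , drop = FALSE]
    sub$tsd_hit <- vapply(seq_len(nrow(sub)), function(i) {
      !is.null(detect_tsd(seq, sub$a5[i], sub$b3[i], params))
    }, logical(1))
    sub <- sub[order(-sub$tsd_hit, -sub$identity,
                     -(sub$b3 - sub$a5), sub$a5), , drop = FALSE]
    used <- logical(0); taken <- list()
    for (i in seq_len(nrow(sub))) {
      ivl <- c(sub$a5[i], sub$b3[i])
      clash <- any(vapply(taken, function(t) {
        ivl[1] <= t[2] && t[1] <= ivl[2]
      }, logical(1)))
      if (clash) next
      taken <- c(taken, list(ivl))
      tsd <- detect_tsd(seq, sub$a5[i], sub$b3[i], params)
      st <- if (is.null(tsd)) sub$a5[i] else tsd$start
      en <- if (is.null(tsd)) sub$b3[i] else tsd$end
      d5 <- st - sub$a5[i]; d3 <- en - sub$b3[i]
      calls <- c(calls, list(data.frame(
        seq_id = seq_id, start = st, end = en, strand = "+",
        category = classify_structure(2L, !is.null(tsd)), n_ltrs = 2L,
        ltr5_start = st, ltr5_end = sub$b5[i] + d5,
        ltr3_start = sub$a3[i] + d3, ltr3_end = en,
        internal_start = sub$b5[i] + d5 + 1L,
        internal_end = sub$a3[i] + d3 - 1L,
        tsd = if (is.null(tsd)) NA_character_ else tsd$tsd,
        identity = sub$identity[i], stringsAsFactors = FALSE)))
    }
  }
  out <- do.call(rbind, calls)
  if (is.null(out)) return(NULL)
  out <- out[n_frac_vec(seq, out$start, out$end) <= params$max_n_frac, ,
             drop = FALSE]
  resolve_overlaps(out)
}

n_frac_vec <- function(seq, start, end) {
  vapply(seq_along(start), function(i) n_frac(seq, start[i], end[i]),
         numeric(1))
}

# among overlapping calls keep TSD-anchored ones first (a chimeric join of
# two neighbouring same-family elements has no TSD), then higher identity,
# longer, leftmost
resolve_overlaps <- function(calls) {
  if (is.null(calls) || nrow(calls) <= 1) return(calls)
  ord <- order(is.na(calls$tsd), -calls$identity,
               -(calls$end - calls$start), calls$start)
  taken <- list(); keep <- logical(nrow(calls))
  for (i in ord) {
    clash <- any(vapply(taken, function(t) {
      calls$seq_id[i] == t$id && calls$start[i] <= t$e && t$s <= calls$end[i]
    }, logical(1)))
    if (clash) next
    keep[i] <- TRUE
    taken <- c(taken, list(list(id = calls$seq_id[i], s = calls$start[i],
                                e = calls$end[i])))
  }
  out <- calls[keep, , drop = FALSE]
  out[order(out$seq_id, out$start), , drop = FALSE]
}

#' Merge periodic multi-LTR loci into complex elements
#'
#' A locus of the form LTR-internal-LTR-internal-LTR is periodic: the
#' element matches itself on diagonals at every multiple of the
#' LTR+internal period. For each two-LTR call, the element sequence is
#' scanned for self-repeat diagonals; when the diagonal set is a ladder
#' `{P, 2P, ..., (n-1)P}` the call is upgraded to a complex element with
#' `n` LTR copies, the outermost two spans re-derived from the largest
#' diagonal.
#'
#' @param calls element call table.
#' @param genome the genome.
#' @param params [detection_params()].
#' @return `calls` with complex loci re-labelled (`category`, `n_ltrs`,
#'   LTR spans updated).
#' @export
detect_complex <- function(calls, genome, params = detection_params()) {
  if (nrow(calls) == 0) return(calls)
  seqs <- as.character(genome)
  for (i in which(calls$n_ltrs == 2)) {
    s <- substr(seqs[[calls$seq_id[i]]], calls$start[i], calls$end[i])
    codes <- dna_codes(s)
    runs <- diagonal_runs(codes, params)
    if (is.null(runs) || nrow(runs) == 0) next
    # keep well-supported self-repeat diagonals of at least LTR size
    runs$len <- runs$hi - runs$lo + 1L
    runs <- runs[runs$len >= params$min_ltr_len, , drop = FALSE]
    if (nrow(runs) == 0) next
    # cluster diagonals, then look for a multiple ladder
    ds <- sort(unique(runs$d))
    ds <- ds[c(TRUE, diff(ds) > 20)]
    period <- ds[1]
    mult <- round(ds / period)
    ok <- abs(ds - mult * period) <= 20
    if (!all(ok) || length(ds) < 2) next
    if (!setequal(mult, seq_along(ds))) next
    dmax <- max(ds)
    n_ltrs <- max(mult) + 1L
    lmax <- max(runs$len[abs(runs$d - dmax) <= 20])
    calls$category[i] <- "complex"
    calls$n_ltrs[i] <- n_ltrs
    calls$ltr5_start[i] <- calls$start[i]
    calls$ltr5_end[i] <- calls$start[i] + lmax - 1L
    calls$ltr3_start[i] <- calls$start[i] + dmax
    calls$ltr3_end[i] <- min(calls$end[i],
                             calls$start[i] + dmax + lmax - 1L)
    calls$internal_start[i] <- calls$ltr5_end[i] + 1L
    calls$internal_end[i] <- calls$ltr3_start[i] - 1L
  }
  calls
}

#' Recover solo LTRs by homology to a library of detected LTRs
#'
#' Scans the genome (both strands) for matches to library LTR sequences at
#' >= `min_identity` over >= `min_cov` of the library LTR length; matches
#' not overlapping an already-called element become solo-LTR calls, with a
#' TSD scan deciding ST versus SnT.
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param ltr_library named character vector (or `DNAStringSet`) of LTR
#'   exemplars, typically the 5' LTRs of intact calls.
#' @param called existing element calls to mask (data.frame or NULL).
#' @param params [detection_params()].
#' @param min_identity,min_cov homology acceptance thresholds.
#' @return data.frame of solo-LTR calls.
#' @export
find_homology_elements <- function(genome, ltr_library, called = NULL,
                                   params = detection_params(),
                                   min_identity = 0.80, min_cov = 0.80) {
  if (length(ltr_library) == 0) return(empty_elements())
  lib <- as.character(ltr_library)
  k <- params$seed_word
  mat <- sub_matrix(1, -1)
  out <- list()
  for (j in seq_along(genome)) {
    seq <- as.character(genome[[j]])
    sid <- names(genome)[j]
    codes <- dna_codes(seq)
    km <- kmer_ends(codes, k)
    idx <- data.table::data.table(code = km, end = seq_along(km))
    idx <- idx[!is.na(idx$code)]
    data.table::setkeyv(idx, "code")
    mask <- called[called$seq_id == sid, , drop = FALSE]
    for (li in seq_along(lib)) {
      for (strand in c("+", "-")) {
        ls <- if (strand == "+") lib[li] else revcomp(lib[li])
        m <- nchar(ls)
        lk <- kmer_ends(dna_codes(ls), k)
        ldt <- data.table::data.table(code = lk, lend = seq_along(lk))
        ldt <- ldt[!is.na(ldt$code)]
        hits <- merge(idx, ldt, by = "code", allow.cartesian = TRUE)
        if (nrow(hits) == 0) next
        hits$diag <- hits$end - hits$lend
        tab <- hits[, list(nseed = .N), by = "diag"]
        tab <- tab[tab$nseed >= 3]
        if (nrow(tab) == 0) next
        tab <- tab[order(tab$diag)]
        grp <- cumsum(c(TRUE, diff(tab$diag) > 30))
        for (g in unique(grp)) {
          dg <- tab$diag[grp == g]
          st <- min(dg) + 1L; en <- max(dg) + m
          if (st < 1 || en > nchar(seq)) next
          if (!is.null(mask) && nrow(mask) > 0 &&
              any(st <= mask$end & mask$start <= en)) next
          gseq <- substr(seq, max(1, st - 20), min(nchar(seq), en + 20))
          al <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(ls), Biostrings::DNAString(gseq),
            type = "local", substitutionMatrix = mat,
            gapOpening = 5, gapExtension = 1)
          alen <- nchar(as.character(Biostrings::alignedPattern(al)))
          ident <- Biostrings::nmatch(al) / alen
          if (ident < min_identity || alen < min_cov * m) next
          # genomic span of the aligned region
          sj <- Biostrings::subject(al)
          gs <- max(1, st - 20) + Biostrings::start(sj) - 1L
          ge <- max(1, st - 20) + Biostrings::end(sj) - 1L
          if (n_frac(seq, gs, ge) > params$max_n_frac) next
          tsd <- detect_tsd(seq, gs, ge, params, jitter_min_len = 5)
          out <- c(out, list(data.frame(
            seq_id = sid,
            start = if (is.null(tsd)) gs else tsd$start,
            end = if (is.null(tsd)) ge else tsd$end,
            strand = strand,
            category = classify_structure(1L, !is.null(tsd)),
            n_ltrs = 1L,
            ltr5_start = if (is.null(tsd)) gs else tsd$start,
            ltr5_end = if (is.null(tsd)) ge else tsd$end,
            ltr3_start = NA_integer_, ltr3_end = NA_integer_,
            internal_start = NA_integer_, internal_end = NA_integer_,
            tsd = if (is.null(tsd)) NA_character_ else tsd$tsd,
            identity = ident, stringsAsFactors = FALSE)))
        }
      }
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_elements())
  resolve_overlaps(out)
}

#' Annotate a genome end-to-end: intact/complex elements plus solo LTRs
#'
#' Runs [find_intact_candidates()], builds the LTR library from the intact
#' calls, runs [find_homology_elements()], and returns one table of calls
#' with stable ids. Detection is deterministic.
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param params [detection_params()].
#' @return data.frame of element calls, ordered by position, with
#'   `element_id`.
#' @export
annotate_genome <- function(genome, params = detection_params()) {
  intact <- find_intact_candidates(genome, params)
  intact <- detect_complex(intact, genome, params)
  lib <- character(0)
  if (nrow(intact) > 0) {
    seqs <- as.character(genome)
    lib <- vapply(seq_len(nrow(intact)), function(i) {
      substr(seqs[[intact$seq_id[i]]], intact$ltr5_start[i],
             intact$ltr5_end[i])
    }, character(1))
    names(lib) <- sprintf("lib%03d", seq_along(lib))
  }
  solos <- find_homology_elements(genome, lib, intact, params)
  all <- rbind(intact, solos)
  if (nrow(all) == 0) {
    all <- empty_elements()
    all$element_id <- character(0)
    return(all)
  }
  all <- all[order(all$seq_id, all$start), , drop = FALSE]
  all$element_id <- sprintf("LTR%04d", seq_len(nrow(all)))
  rownames(all) <- NULL
  all[, c("element_id", setdiff(names(all), "element_id"))]
}

#' Extract LTR (and internal) sequences for an element table
#'
#' @param elements element call table.
#' @param genome the genome.
#' @return `elements` with character columns `ltr5_seq`, `ltr3_seq`.
#' @export
element_sequences <- function(elements, genome) {
  seqs <- as.character(genome)
  elements$ltr5_seq <- vapply(seq_len(nrow(elements)), function(i) {
    substr(seqs[[elements$seq_id[i]]], elements$ltr5_start[i],
           elements$ltr5_end[i])
  }, character(1))
  elements$ltr3_seq <- vapply(seq_len(nrow(elements)), function(i) {
    if (is.na(elements$ltr3_start[i])) return(NA_character_)
    substr(seqs[[elements$seq_id[i]]], elements$ltr3_start[i],
           elements$ltr3_end[i])
  }, character(1))
  elements
}
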