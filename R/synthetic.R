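# Synthetic genomes with planted LTR retrotransposons and known ground truth.
#
# The generator emulates the anatomy the annotator is built to find: intact
# elements (TSD + LTR + internal + LTR' + TSD) whose two LTRs have been
# diverged to a requested per-site K, solo LTRs, multi-LTR "complex" loci,
# and a second genome carrying a chosen fraction of the insertions at
# homologous loci plus genome-wide point divergence.

CODONS <- NULL  # filled lazily

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  list(codons = names(gc), aa = unname(gc),
       sense = names(gc)[gc != "*"])
}

# reverse-translate a peptide, sampling a codon per residue from the caller's RNG
reverse_translate <- function(peptide) {
  ct <- codon_table()
  aa <- strsplit(peptide, "")[[1]]
  paste(vapply(aa, function(a) {
    opts <- ct$codons[ct$aa == a]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

#' Bundled synthetic INT/RT peptide motifs
#'
#' One integrase (INT) and one reverse-transcriptase (RT) core peptide per
#' autonomous superfamily. These are synthetic stand-ins written around the
#' canonical conserved blocks of each domain (e.g. the `SLYGLKQ`/`YXDD`
#' boxes of RT); they are shipped as a replaceable data file, not as curated
#' database entries.
#'
#' @return data.frame with columns `superfamily`, `domain`, `peptide`.
#' @export
bundled_motifs <- function() {
  p <- system.file("extdata", "domain_motifs_synthetic.tsv",
                   package = "ltrscape")
  utils::read.delim(p, stringsAsFactors = FALSE)
}

#' Bundled synthetic lineage reference RT sequences
#'
#' Thirteen reference reverse-transcriptase nucleotide sequences, one per
#' named Copia lineage (Ale, Ivana, Bianca, Angela, TAR, Maximus) and Gypsy
#' lineage (Tekay, Galadriel, CRM, Reina, Athila, Ogre, Tat). They are
#' synthetic: each is the superfamily RT core peptide reverse-translated
#' with lineage-specific codon choices inside lineage-specific flanking
#' codons. The file is an input and can be replaced by a curated reference
#' set with the same `name|superfamily` header convention.
#'
#' @return data.frame with columns `lineage`, `superfamily`, `seq`.
#' @export
bundled_lineage_refs <- function() {
  p <- system.file("extdata", "lineage_refs_synthetic.fasta",
                   package = "ltrscape")
  x <- Biostrings::readDNAStringSet(p)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  data.frame(lineage = vapply(parts, `[`, "", 1),
             superfamily = vapply(parts, `[`, "", 2),
             seq = as.character(x), stringsAsFactors = FALSE)
}

#' Generate an i.i.d. background genome
#'
#' @param length sequence length in bp.
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed; generation is deterministic given the seed.
#' @param gaps optional data.frame (`start`, `length`) of N-gap blocks to
#'   stamp into the sequence (1-based starts).
#' @param id sequence name.
#' @return A single-record [Biostrings::DNAStringSet].
#' @export
generate_background <- function(length, gc = 0.5, seed, gaps = NULL,
                                id = "chr1") {
  stopifnot(length > 0, gc > 0, gc < 1)
  set.seed(seed)
  s <- random_dna(length, gc)
  if (!is.null(gaps) && nrow(gaps) > 0) {
    for (i in seq_len(nrow(gaps))) {
      st <- gaps$start[i]; ln <- gaps$length[i]
      stopifnot(st >= 1, st + ln - 1 <= length)
      substr(s, st, st + ln - 1) <- strrep("N", ln)
    }
  }
  out <- Biostrings::DNAStringSet(s)
  names(out) <- id
  out
}

#' Specification of what to plant in a synthetic genome
#'
#' @param n_intact intact elements with TSDs (IT).
#' @param n_solo solo LTRs with TSDs (ST).
#' @param n_intact_notsd intact elements without TSDs (InT).
#' @param n_solo_notsd solo LTRs without TSDs (SnT).
#' @param n_complex multi-LTR complex loci (LTR-internal-LTR-internal-LTR).
#' @param complex_n_ltrs LTR copies per complex locus (>= 3).
#' @param ltr_len_range LTR length range in bp.
#' @param internal_len_range internal-region length range for autonomous
#'   (Copia/Gypsy) families, bp.
#' @param tsd_len_range allowed TSD lengths (subset of 4:6).
#' @param target_K per-site divergence planted between the two LTRs of an
#'   element (Jukes-Cantor scale).
#' @param superfamily_profile named proportions over
#'   `c("Copia","Gypsy","TRIM","LARD")`; must sum to 1.
#' @param n_families number of distinct families to simulate.
#' @param family_drift per-site divergence of each element copy from its
#'   family ancestor (shared by both LTRs, i.e. present at insertion).
#' @param min_sep minimum distance between planted insertions, bp.
#' @param min_flank minimum distance from a sequence end, bp.
#' @param seed integer seed (mandatory).
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(n_intact = 40, n_solo = 10, n_intact_notsd = 5,
                       n_solo_notsd = 5, n_complex = 0, complex_n_ltrs = 3,
                       ltr_len_range = c(200, 600),
                       internal_len_range = c(2000, 6000),
                       tsd_len_range = 4:6, target_K = 0.02,
                       superfamily_profile = c(Copia = 0.4, Gypsy = 0.3,
                                               TRIM = 0.2, LARD = 0.1),
                       n_families = 6, family_drift = 0.01,
                       min_sep = 1500, min_flank = 1000, seed) {
  stopifnot(all(c(n_intact, n_solo, n_intact_notsd, n_solo_notsd,
                  n_complex) >= 0),
            target_K >= 0, target_K <= 0.5,
            all(tsd_len_range %in% 4:6), complex_n_ltrs >= 3,
            abs(sum(superfamily_profile) - 1) < 1e-8,
            !missing(seed))
  structure(as.list(environment()), class = "plant_spec")
}

# Build the ancestral family panel: per family an LTR, an internal region
# (with INT/RT domains for Copia/Gypsy in the superfamily-defining order),
# a superfamily and a lineage. Uses the active RNG stream.
build_family_panel <- function(spec) {
  motifs <- bundled_motifs()
  refs <- bundled_lineage_refs()
  sfs <- sample(names(spec$superfamily_profile), spec$n_families,
                replace = TRUE, prob = spec$superfamily_profile)
  # guarantee at least one autonomous family so motif tests are exercised,
  # and one TRIM family when complex elements are requested (complex
  # multi-LTR loci are a TRIM phenomenon)
  if (!any(sfs %in% c("Copia", "Gypsy"))) sfs[1] <- "Copia"
  if (spec$n_complex > 0 && !any(sfs == "TRIM")) {
    sfs[length(sfs)] <- "TRIM"
  }
  fams <- lapply(seq_along(sfs), function(i) {
    sf <- sfs[i]
    if (sf == "TRIM") {
      ltr_len <- sample(150:300, 1)
      internal <- random_dna(sample(300:800, 1))
      lineage <- NA_character_
    } else if (sf == "LARD") {
      ltr_len <- sample(spec$ltr_len_range[1]:spec$ltr_len_range[2], 1)
      internal <- random_dna(sample(4200:6000, 1))
      lineage <- NA_character_
    } else {
      ltr_len <- sample(spec$ltr_len_range[1]:spec$ltr_len_range[2], 1)
      rs <- refs[refs$superfamily == sf, ]
      pick <- rs[sample.int(nrow(rs), 1), ]
      lineage <- pick$lineage
      rt_nt <- mutate_sites(pick$seq, 0.05)
      int_pep <- motifs$peptide[motifs$superfamily == sf &
                                  motifs$domain == "INT"]
      int_nt <- reverse_translate(int_pep)
      len <- sample(spec$internal_len_range[1]:spec$internal_len_range[2], 1)
      core <- if (sf == "Copia") paste0(int_nt, random_dna(90), rt_nt)
              else paste0(rt_nt, random_dna(90), int_nt)
      pad <- max(0, len - nchar(core) - 200)
      internal <- paste0(random_dna(200), core, random_dna(pad))
    }
    list(family = sprintf("F%02d", i), superfamily = sf, lineage = lineage,
         ltr = random_dna(ltr_len), internal = internal)
  })
  names(fams) <- vapply(fams, `[[`, "", "family")
  fams
}

p_mismatch <- function(a, b) {
  ca <- dna_codes(a); cb <- dna_codes(b)
  ok <- !is.na(ca) & !is.na(cb)
  if (!any(ok)) return(NA_real_)
  mean(ca[ok] != cb[ok])
}

#' Plant LTR retrotransposons into a background genome
#'
#' Each intact element is inserted as `TSD + LTR + internal + LTR' + TSD`
#' where the TSD is the duplicated target site taken from the insertion
#' point and `LTR'` is the element's LTR mutated to the requested `target_K`
#' under uniform random substitutions. Solo LTRs are a single LTR copy
#' (with or without TSD); complex loci carry `complex_n_ltrs` alternating
#' LTR/internal segments under one outer TSD pair. The manifest records the
#' realized (post-mutation) LTR-LTR divergence of every multi-LTR element.
#'
#' @param genome [Biostrings::DNAStringSet] background.
#' @param spec a [plant_spec()].
#' @return `list(genome =, manifest =)`; manifest is a data.frame with one
#'   row per planted element (1-based inclusive coordinates on the output
#'   genome, element span excluding TSDs).
#' @export
plant_elements <- function(genome, spec) {
  stopifnot(inherits(spec, "plant_spec"))
  set.seed(spec$seed)
  fams <- build_family_panel(spec)
  cats <- c(rep("IT", spec$n_intact), rep("ST", spec$n_solo),
            rep("InT", spec$n_intact_notsd), rep("SnT", spec$n_solo_notsd),
            rep("complex", spec$n_complex))
  n <- length(cats)
  if (n == 0) {
    return(list(genome = genome, manifest = empty_manifest()))
  }
  cats <- sample(cats)  # interleave categories along the genome

  # choose insertion points: uniform over non-N space, min separation
  lens <- Biostrings::width(genome)
  chr <- sample(seq_along(genome), n, replace = TRUE, prob = lens)
  pos <- integer(n)
  seqs <- as.character(genome)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:2000) {
      p <- sample.int(lens[chr[i]] - 2L * spec$min_flank, 1L) + spec$min_flank
      win <- substr(seqs[[chr[i]]], p - 10, p + 10)
      if (grepl("N", win, fixed = TRUE)) next
      prev <- which(chr[seq_len(i - 1)] == chr[i])
      if (length(prev) == 0 || all(abs(pos[prev] - p) >= spec$min_sep)) {
        pos[i] <- p; ok <- TRUE; break
      }
    }
    if (!ok) stop("infeasible packing: could not place ", n,
                  " insertions with min_sep=", spec$min_sep,
                  " in ", sum(lens), " bp")
  }

  man <- vector("list", n)
  build <- lapply(seq_along(genome), function(j) list())
  trim_fams <- which(vapply(fams, `[[`, "", "superfamily") == "TRIM")
  for (i in order(chr, pos)) {
    cat_i <- cats[i]
    fam <- if (cat_i == "complex" && length(trim_fams) > 0) {
      fams[[trim_fams[sample.int(length(trim_fams), 1L)]]]
    } else {
      fams[[sample.int(length(fams), 1L)]]
    }
    has_tsd <- cat_i %in% c("IT", "ST", "complex")
    tsd_len <- spec$tsd_len_range[sample.int(length(spec$tsd_len_range), 1L)]
    tsd <- if (has_tsd) substr(seqs[[chr[i]]], pos[i], pos[i] + tsd_len - 1L)
           else NA_character_
    base_ltr <- mutate_sites(fam$ltr, spec$family_drift)
    p_age <- jc_invert(spec$target_K)
    if (cat_i %in% c("IT", "InT")) {
      ltr5 <- base_ltr
      ltr3 <- mutate_sites(base_ltr, p_age)
      internal <- mutate_sites(fam$internal, spec$family_drift)
      body <- paste0(ltr5, internal, ltr3)
      n_ltrs <- 2L
      ltr_offsets <- c(0L, nchar(ltr5) + nchar(internal))
      realized <- jc_correct(p_mismatch(ltr5, ltr3))
    } else if (cat_i %in% c("ST", "SnT")) {
      ltr5 <- mutate_sites(base_ltr, p_age / 2)
      body <- ltr5
      n_ltrs <- 1L
      ltr_offsets <- 0L
      realized <- NA_real_
    } else {  # complex
      copies <- replicate(spec$complex_n_ltrs,
                          mutate_sites(base_ltr, p_age / 2))
      internal <- mutate_sites(fam$internal, spec$family_drift)
      parts <- character(0)
      ltr_offsets <- integer(0)
      off <- 0L
      for (k in seq_along(copies)) {
        ltr_offsets <- c(ltr_offsets, off)
        parts <- c(parts, copies[k])
        off <- off + nchar(copies[k])
        if (k < length(copies)) {
          parts <- c(parts, internal)
          off <- off + nchar(internal)
        }
      }
      body <- paste(parts, collapse = "")
      n_ltrs <- spec$complex_n_ltrs
      realized <- jc_correct(p_mismatch(copies[1], copies[2]))
    }
    ins <- if (has_tsd) paste0(body, tsd) else body
    build[[chr[i]]] <- c(build[[chr[i]]],
                         list(list(pos = pos[i], ins = ins, i = i)))
    man[[i]] <- data.frame(
      truth_id = sprintf("t%04d", i), seq_id = names(genome)[chr[i]],
      cut_pos = pos[i], body_len = nchar(body),
      category = cat_i, n_ltrs = n_ltrs,
      family = fam$family, superfamily = fam$superfamily,
      lineage = fam$lineage, tsd = tsd,
      ltr_len = nchar(base_ltr),
      ltr_off = paste(ltr_offsets, collapse = ","),
      target_K = spec$target_K, realized_K = realized,
      stringsAsFactors = FALSE)
  }
  man <- do.call(rbind, man)

  # assemble each chromosome left-to-right, tracking final coordinates
  out_seqs <- character(length(genome))
  man$start <- NA_integer_; man$end <- NA_integer_
  for (j in seq_along(genome)) {
    items <- build[[j]]
    if (length(items) == 0) { out_seqs[j] <- seqs[[j]]; next }
    ord <- order(vapply(items, `[[`, 0, "pos"))
    items <- items[ord]
    pieces <- character(0); cursor <- 1L; offset <- 0L
    for (it in items) {
      pieces <- c(pieces, substr(seqs[[j]], cursor, it$pos - 1L))
      row <- which(man$truth_id == sprintf("t%04d", it$i))
      tsd_len <- if (is.na(man$tsd[row])) 0L else nchar(man$tsd[row])
      # insertion goes after the original target site (pos..pos+tsd_len-1)
      pieces <- c(pieces, substr(seqs[[j]], it$pos, it$pos + tsd_len - 1L))
      elem_start <- it$pos + offset + tsd_len
      pieces <- c(pieces, it$ins)
      man$start[row] <- elem_start
      man$end[row] <- elem_start + man$body_len[row] - 1L
      offset <- offset + nchar(it$ins)
      cursor <- it$pos + tsd_len
    }
    pieces <- c(pieces, substr(seqs[[j]], cursor, nchar(seqs[[j]])))
    out_seqs[j] <- paste(pieces, collapse = "")
  }
  g2 <- Biostrings::DNAStringSet(out_seqs)
  names(g2) <- names(genome)

  # absolute LTR spans
  offs <- strsplit(man$ltr_off, ",")
  man$ltr5_start <- man$start + as.integer(vapply(offs, `[`, "", 1))
  man$ltr5_end <- man$ltr5_start + man$ltr_len - 1L
  last <- vapply(offs, function(x) as.integer(x[length(x)]), 0L)
  man$ltr3_start <- ifelse(man$n_ltrs >= 2, man$start + last, NA_integer_)
  man$ltr3_end <- ifelse(man$n_ltrs >= 2, man$ltr3_start + man$ltr_len - 1L,
                         NA_integer_)
  man$ortholog_id <- NA_character_
  man$cut_pos <- NULL; man$body_len <- NULL; man$ltr_off <- NULL
  rownames(man) <- NULL
  list(genome = g2, manifest = man)
}

empty_manifest <- function() {
  data.frame(truth_id = character(), seq_id = character(),
             category = character(), n_ltrs = integer(),
             family = character(), superfamily = character(),
             lineage = character(), tsd = character(),
             ltr_len = integer(), target_K = numeric(),
             realized_K = numeric(), start = integer(), end = integer(),
             ltr5_start = integer(), ltr5_end = integer(),
             ltr3_start = integer(), ltr3_end = integer(),
             ortholog_id = character(), stringsAsFactors = FALSE)
}

#' Derive a second genome carrying a subset of orthologous insertions
#'
#' A fraction of the planted insertions is retained at homologous loci in
#' the second genome; the rest are excised cleanly (flanks rejoined, one
#' TSD copy restored to the single ancestral target site). Genome-wide
#' point substitutions at `point_divergence` (JC scale) are then applied
#' independently to both genomes, so expected inter-genome divergence at
#' homologous sites is twice `point_divergence`.
#'
#' @param genome planted genome A from [plant_elements()].
#' @param manifest its manifest.
#' @param ortholog_fraction probability each insertion is retained in B.
#' @param point_divergence per-genome per-site divergence applied after the
#'   split (JC scale).
#' @param seed integer seed.
#' @return `list(genome_a, genome_b, manifest_a, manifest_b)`; both
#'   manifests carry `ortholog_id` links for retained insertions, and
#'   `realized_K` is re-measured on the mutated genomes.
#' @export
diverge_genomes <- function(genome, manifest, ortholog_fraction = 0.5,
                            point_divergence = 0.01, seed) {
  set.seed(seed)
  keep <- runif(nrow(manifest)) < ortholog_fraction
  seqs <- as.character(genome)
  man_b <- manifest[keep, , drop = FALSE]
  out <- character(length(genome))
  for (j in seq_along(genome)) {
    rows <- which(manifest$seq_id == names(genome)[j])
    rows <- rows[order(manifest$start[rows])]
    pieces <- character(0); cursor <- 1L; offset <- 0L
    for (r in rows) {
      tsd_len <- if (is.na(manifest$tsd[r])) 0L else nchar(manifest$tsd[r])
      if (keep[r]) {
        bi <- which(man_b$truth_id == manifest$truth_id[r])
        man_b$start[bi] <- manifest$start[r] + offset
        man_b$end[bi] <- manifest$end[r] + offset
        for (cl in c("ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end")) {
          man_b[[cl]][bi] <- manifest[[cl]][r] + offset
        }
        next
      }
      # excise element plus the duplicated (right) TSD copy
      pieces <- c(pieces, substr(seqs[[j]], cursor, manifest$start[r] - 1L))
      cursor <- manifest$end[r] + tsd_len + 1L
      offset <- offset - (manifest$end[r] - manifest$start[r] + 1L) - tsd_len
    }
    pieces <- c(pieces, substr(seqs[[j]], cursor, nchar(seqs[[j]])))
    out[j] <- paste(pieces, collapse = "")
  }
  p <- jc_invert(point_divergence)
  ga <- vapply(as.character(genome), mutate_sites, character(1), p = p)
  gb <- vapply(out, mutate_sites, character(1), p = p)
  genome_a <- Biostrings::DNAStringSet(unname(ga))
  names(genome_a) <- names(genome)
  genome_b <- Biostrings::DNAStringSet(unname(gb))
  names(genome_b) <- names(genome)

  man_a <- manifest
  man_a$ortholog_id <- ifelse(keep, man_a$truth_id, NA_character_)
  man_b$ortholog_id <- man_b$truth_id
  # re-measure realized intra-element divergence after point mutations
  remeasure <- function(man, g) {
    s <- as.character(g)
    for (i in which(man$n_ltrs >= 2)) {
      a <- substr(s[[man$seq_id[i]]], man$ltr5_start[i], man$ltr5_end[i])
      b <- substr(s[[man$seq_id[i]]], man$ltr3_start[i], man$ltr3_end[i])
      man$realized_K[i] <- jc_correct(p_mismatch(a, b))
    }
    man
  }
  man_a <- remeasure(man_a, genome_a)
  man_b <- remeasure(man_b, genome_b)
  rownames(man_b) <- NULL
  list(genome_a = genome_a, genome_b = genome_b,
       manifest_a = man_a, manifest_b = man_b)
}

#' Generate paired in-frame CDS with controlled synonymous divergence
#'
#' Ancestral coding sequences are built from sense codons; copy B receives
#' a Poisson number of synonymous changes targeting an expected NG86
#' `Ks = ks_target` and nonsynonymous changes targeting
#' `Ka = omega * ks_target`. Changes are single-nucleotide, stop-avoiding,
#' and placed in distinct codons wherever possible.
#'
#' @param n number of pairs.
#' @param ks_target expected synonymous divergence per synonymous site.
#' @param omega target Ka/Ks ratio.
#' @param codons codons per CDS (> 10).
#' @param seed integer seed.
#' @return `list(a =, b =)` of [Biostrings::DNAStringSet] with matched names.
#' @export
generate_gene_pairs <- function(n, ks_target = 0.02, omega = 0.2,
                                codons = 300, seed) {
  stopifnot(n > 0, codons > 10, ks_target >= 0, omega >= 0)
  set.seed(seed)
  ct <- codon_table()
  a_list <- character(n); b_list <- character(n)
  for (i in seq_len(n)) {
    cod <- sample(ct$sense, codons, replace = TRUE)
    sites <- ng86_sites(paste(cod, collapse = ""))
    nsyn <- rpois(1, ks_target * sites$S)
    nnon <- rpois(1, omega * ks_target * sites$N)
    cod_b <- cod
    used <- integer(0)
    apply_changes <- function(k, synonymous) {
      placed <- 0L; guard <- 0L
      while (placed < k && guard < 50L * k + 200L) {
        guard <- guard + 1L
        j <- sample.int(codons, 1L)
        if (j %in% used) next
        vars <- single_nt_variants(cod_b[j])
        aa0 <- ct$aa[match(cod_b[j], ct$codons)]
        va <- ct$aa[match(vars, ct$codons)]
        ok <- if (synonymous) vars[va == aa0] else vars[va != aa0 & va != "*"]
        if (length(ok) == 0) next
        cod_b[j] <<- ok[sample.int(length(ok), 1L)]
        used <<- c(used, j)
        placed <- placed + 1L
      }
    }
    apply_changes(nsyn, TRUE)
    apply_changes(nnon, FALSE)
    a_list[i] <- paste(cod, collapse = "")
    b_list[i] <- paste(cod_b, collapse = "")
  }
  nm <- sprintf("g%04d", seq_len(n))
  a <- Biostrings::DNAStringSet(a_list); names(a) <- nm
  b <- Biostrings::DNAStringSet(b_list); names(b) <- nm
  list(a = a, b = b)
}

single_nt_variants <- function(codon) {
  nt <- c("A", "C", "G", "T")
  out <- character(0)
  for (p in 1:3) {
    for (x in setdiff(nt, substr(codon, p, p))) {
      v <- codon
      substr(v, p, p) <- x
      out <- c(out, v)
    }
  }
  out
}

#' Write a ground-truth manifest as TSV
#' @param manifest manifest data.frame.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
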