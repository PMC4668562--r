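# End-to-end orchestration on synthetic genomes, with evaluation of calls
# against the planted ground truth.

#' Default pipeline configuration
#'
#' A single master seed drives every stochastic stage through
#' [derive_seed()]. All stage parameters are exposed here; rates default
#' to 1.3e-8 (LTRs) and 6.03e-9 (genes) substitutions per site per year.
#'
#' @param seed master seed.
#' @param genome_length background genome length, bp.
#' @param gc background GC fraction.
#' @param spec_args list of overrides for [plant_spec()].
#' @param window_size randomization-test window, bp.
#' @param n_sim randomization simulations.
#' @param r_ltr,r_gene substitution rates per site per year.
#' @param compare run the two-genome orthology stage.
#' @param ortholog_fraction,point_divergence passed to [diverge_genomes()].
#' @param lineage run lineage assignment.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(seed, genome_length = 5e6, gc = 0.38,
                       spec_args = list(), window_size = 1e5,
                       n_sim = 2000, r_ltr = 1.3e-8, r_gene = 6.03e-9,
                       compare = TRUE, ortholog_fraction = 0.5,
                       point_divergence = 0.01, lineage = TRUE) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline on a synthetic genome
#'
#' simulate -> annotate -> classify -> date -> distribution ->
#' (compare) -> (lineage), returning a report of all summary statistics
#' plus an evaluation block against the planted truth. Deterministic for
#' a fixed config.
#'
#' @param config a [run_config()].
#' @return Nested list report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  bg <- generate_background(config$genome_length, config$gc,
                            seed = derive_seed(config$seed, "background"))
  sp <- do.call(plant_spec, c(list(seed = derive_seed(config$seed, "plant")),
                              config$spec_args))
  planted <- plant_elements(bg, sp)
  genome <- planted$genome
  manifest <- planted$manifest
  orth_block <- NULL
  if (config$compare) {
    div <- diverge_genomes(genome, manifest,
                           ortholog_fraction = config$ortholog_fraction,
                           point_divergence = config$point_divergence,
                           seed = derive_seed(config$seed, "diverge"))
    genome <- div$genome_a
    manifest <- div$manifest_a
  }

  elements <- annotate_genome(genome)
  cls <- classify_elements(elements, genome)
  elements <- date_elements(cls$elements, genome, r = config$r_ltr)
  summary_tab <- summarize_superfamilies(elements)

  win <- window_counts(elements, genome, config$window_size)
  rnd <- randomization_test(win, n_sim = config$n_sim,
                            seed = derive_seed(config$seed, "randomization"))

  if (config$compare) {
    calls <- ortholog_calls(elements, genome, div$genome_b)
    contrast <- tryCatch(intra_inter_contrast(calls),
                         error = function(e) NULL)
    orth_block <- list(calls = calls, contrast = contrast,
                       n_orthologous = sum(calls$status == "orthologous"))
  }

  fams <- cls$families
  if (config$lineage) fams <- assign_lineages(fams)

  eval_block <- evaluate_against_truth(elements, manifest)
  if (config$compare) {
    eval_block$ortholog_links <- evaluate_ortholog_links(
      orth_block$calls, elements, manifest)
  }

  list(config = unclass(config),
       truth = list(manifest = manifest),
       annotation = list(elements = elements, n_calls = nrow(elements)),
       classification = list(families = fams, summary = summary_tab),
       dating = list(
         mean_K_IT = mean(elements$K[elements$category == "IT"],
                          na.rm = TRUE),
         mean_age_my_IT = mean(elements$age_my[elements$category == "IT"],
                               na.rm = TRUE)),
       distribution = rnd$summary,
       orthology = orth_block,
       evaluation = eval_block)
}

# 50%-reciprocal-overlap matching between one call set and truth records
match_truth <- function(calls, manifest) {
  if (nrow(calls) == 0 || nrow(manifest) == 0) return(NULL)
  out <- list()
  for (i in seq_len(nrow(calls))) {
    cand <- which(manifest$seq_id == calls$seq_id[i] &
                    manifest$start <= calls$end[i] &
                    calls$start[i] <= manifest$end)
    for (m in cand) {
      ov <- min(calls$end[i], manifest$end[m]) -
        max(calls$start[i], manifest$start[m]) + 1
      if (ov >= 0.5 * (calls$end[i] - calls$start[i] + 1) &&
          ov >= 0.5 * (manifest$end[m] - manifest$start[m] + 1)) {
        out <- c(out, list(data.frame(call = i, truth = m, overlap = ov)))
      }
    }
  }
  do.call(rbind, out)
}

#' Evaluate annotation calls against a planted ground-truth manifest
#'
#' Calls are matched to truth records by 50% reciprocal overlap. Reports
#' per-category precision/recall, boundary mean absolute error over
#' matched pairs, and the adjusted Rand index between called and planted
#' family partitions (over matched calls).
#'
#' @param calls element table from [annotate_genome()] (family column
#'   optional).
#' @param manifest truth manifest from [plant_elements()].
#' @return list with `per_category`, `boundary_mae`, `family_ari`.
#' @export
evaluate_against_truth <- function(calls, manifest) {
  mt <- match_truth(calls, manifest)
  cats <- c("IT", "ST", "InT", "SnT", "complex")
  per_cat <- lapply(cats, function(ct) {
    truth_rows <- which(manifest$category == ct)
    call_rows <- which(calls$category == ct)
    tp <- 0L
    if (!is.null(mt)) {
      tp <- sum(mt$truth %in% truth_rows & mt$call %in% call_rows &
                  !duplicated(mt$truth))
    }
    data.frame(category = ct, n_truth = length(truth_rows),
               n_called = length(call_rows), tp = tp,
               precision = if (length(call_rows)) tp / length(call_rows)
                           else NA_real_,
               recall = if (length(truth_rows)) tp / length(truth_rows)
                        else NA_real_, stringsAsFactors = FALSE)
  })
  per_cat <- do.call(rbind, per_cat)
  bmae <- NA_real_
  ari <- NA_real_
  if (!is.null(mt) && nrow(mt) > 0) {
    bmae <- mean(abs(calls$start[mt$call] - manifest$start[mt$truth]) +
                   abs(calls$end[mt$call] - manifest$end[mt$truth])) / 2
    if ("family_id" %in% names(calls) &&
        requireNamespace("mclust", quietly = TRUE)) {
      ari <- mclust::adjustedRandIndex(calls$family_id[mt$call],
                                       manifest$family[mt$truth])
    }
  }
  list(per_category = per_cat, boundary_mae = bmae, family_ari = ari,
       matches = mt)
}

# precision/recall of orthologous-status calls against manifest links
evaluate_ortholog_links <- function(calls, elements, manifest) {
  mt <- match_truth(elements, manifest)
  if (is.null(mt)) return(list(precision = NA_real_, recall = NA_real_))
  truth_link <- !is.na(manifest$ortholog_id[mt$truth])
  idx <- match(elements$element_id[mt$call], calls$element_id)
  status <- calls$status[idx]
  usable <- !is.na(status) & !startsWith(status, "skipped")
  called_orth <- usable & status == "orthologous"
  tp <- sum(called_orth & truth_link)
  list(precision = if (sum(called_orth)) tp / sum(called_orth) else NA,
       recall = if (sum(truth_link & usable)) {
         tp / sum(truth_link & usable)
       } else NA,
       n_usable = sum(usable))
}

#' Write a pipeline report as JSON
#'
#' Data-frame heavy blocks are reduced to their summary statistics so the
#' report stays a readable, versioned JSON document.
#'
#' @param report list from [run_pipeline()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_report <- function(report, path) {
  slim <- report
  slim$truth <- list(n_planted = nrow(report$truth$manifest))
  slim$annotation$elements <- NULL
  slim$classification$families <-
    as.list(table(report$classification$families$superfamily))
  if (!is.null(slim$orthology)) slim$orthology$calls <- NULL
  slim$evaluation$matches <- NULL
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
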