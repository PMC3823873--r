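# Retrospective scoring of identification results against a truth
# taxonomy, threshold sweeps, and the species-discovery assessment.

SCORE_CATEGORIES <- c("success", "correctly_flagged_new",
                      "correctly_flagged_known_complex", "incorrectly_flagged",
                      "misidentified_or_not_flagged", "ambiguous", "no_match")

# A flagged query (no match, or an NJ new-species candidate) is judged
# against the truth taxonomy: new if its truth species has no reference
# left, part of a known complex if its evaluation label lumps >= 2 truth
# species, otherwise incorrectly flagged.
.classify_flag <- function(q, eval_tax, truth_tax, ref_truth_species) {
  tl <- truth_tax$label_of[q]
  if (is.na(tl)) stop("query ", q, " has no label in the truth taxonomy")
  el <- eval_tax$label_of[q]
  cm <- eval_tax$complex_map[[el]]
  if (!is.null(cm) && length(cm) >= 2L && tl %in% cm)
    return("correctly_flagged_known_complex")
  if (!tl %in% ref_truth_species) return("correctly_flagged_new")
  "incorrectly_flagged"
}

#' Score identification results against a truth taxonomy
#'
#' Success, misidentification and (non-flag) ambiguity pass through from
#' the evaluation taxonomy; flagged queries (no match, or NJ new-species
#' candidates) are checked against the truth taxonomy and split into
#' correctly flagged new species, correctly flagged members of a known
#' complex, and incorrect flags.
#'
#' @param results data.frame from [identify_specimens()] (one method, one
#'   threshold).
#' @param eval_tax the `TaxonomyMap` the identification ran under.
#' @param truth_tax the `TaxonomyMap` holding the accepted (truth) labels.
#' @param ref_ids specimens available as references (default: every
#'   specimen labelled in `eval_tax`); a query's own record is ignored
#'   when deciding whether its truth species was referenced.
#' @return one-row data.frame of class `SummaryTable`: method, threshold,
#'   `n_scored`, one count column per category and matching `pct_*`
#'   columns (percentages recomputed from the counts).
#' @export
score_against_truth <- function(results, eval_tax, truth_tax, ref_ids = NULL) {
  stopifnot(is.data.frame(results))
  if (length(unique(results$method)) > 1L)
    stop("score one method at a time (see threshold_sweep)")
  if (is.null(ref_ids)) ref_ids <- names(eval_tax$label_of)
  truth_of_refs <- function(q)
    unique(unname(truth_tax$label_of[setdiff(ref_ids, q)]))
  cat_of <- character(nrow(results))
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    flagged_ambiguous <- identical(r$outcome, "ambiguous") &&
      identical(r$note, "new_candidate")
    cat_of[i] <-
      if (identical(r$outcome, "success")) "success"
      else if (identical(r$outcome, "misidentified")) "misidentified_or_not_flagged"
      else if (identical(r$outcome, "no_match") || flagged_ambiguous)
        .classify_flag(r$query_id, eval_tax, truth_tax,
                       truth_of_refs(r$query_id))
      else "ambiguous"
  }
  counts <- table(factor(cat_of, levels = SCORE_CATEGORIES))
  n <- nrow(results)
  out <- data.frame(method = results$method[1L],
                    threshold = results$threshold[1L], n_scored = n)
  for (cc in SCORE_CATEGORIES) out[[cc]] <- as.integer(counts[[cc]])
  for (cc in SCORE_CATEGORIES) out[[paste0("pct_", cc)]] <- 100 * counts[[cc]] / n
  class(out) <- c("SummaryTable", "data.frame")
  out
}

#' Threshold sweep over identification methods
#'
#' Runs each requested method at each threshold (the NJ method, which has
#' no threshold, runs once) and scores every run against the truth
#' taxonomy.
#'
#' @param m a `DistanceMatrix` over the dataset.
#' @param eval_tax,truth_tax evaluation and truth `TaxonomyMap`s.
#' @param methods methods to run (see [identify_specimens()]).
#' @param thresholds numeric thresholds in substitutions/site
#'   (default 2-10%).
#' @param tree NJ tree, required when "nj" is among the methods.
#' @param queries optional query subset.
#' @param score_exemplar_queries whether exemplar specimens are scored as
#'   queries under the exemplar method. The default (FALSE) matches the
#'   usual summary-table convention where the per-category counts cover
#'   the non-exemplar specimens; per-query runs via
#'   [identify_specimens()] default to scoring them.
#' @return data.frame (rows = method x threshold) of `SummaryTable` rows.
#' @export
threshold_sweep <- function(m, eval_tax, truth_tax,
                            methods = c("best_match", "best_close_match",
                                        "all_species_barcodes", "exemplar"),
                            thresholds = c(0.02, 0.04, 0.06, 0.08, 0.10),
                            tree = NULL, queries = NULL,
                            score_exemplar_queries = FALSE) {
  out <- list()
  for (meth in methods) {
    th <- if (meth %in% c("best_match", "nj")) NA_real_ else thresholds
    for (t in th) {
      res <- identify_specimens(m, eval_tax, meth,
                                threshold = if (is.na(t)) NULL else t,
                                queries = queries, tree = tree,
                                score_exemplar_queries = score_exemplar_queries)
      ref_ids <- if (meth %in% c("exemplar", "nj"))
        unname(eval_tax$exemplar_of) else NULL
      out[[length(out) + 1L]] <-
        score_against_truth(res, eval_tax, truth_tax, ref_ids = ref_ids)
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

DISCOVERY_CATEGORIES <- c("correctly_grouped_existing", "correctly_flagged_new",
                          "correctly_flagged_part_of_complex",
                          "incorrectly_flagged_new", "incorrectly_lumped")

#' Species-discovery assessment
#'
#' References are restricted to specimens already known under the
#' historic taxonomy (`discovery_status == "known_historic"`); queries are
#' the specimens of suspected new taxa or new forms. Each query lands in
#' exactly one category: a flagged query is correct when the truth calls
#' it a new taxon (or a member of a complex that was then unrecognised)
#' and incorrect when it is just a new form of an existing species; a
#' query grouped with an existing species is correct for a new form and
#' an incorrect lumping for a new taxon.
#'
#' @param m a `DistanceMatrix` over references and queries.
#' @param tax `TaxonomyMap` carrying truth labels, exemplars and
#'   `discovery_status_of` for every specimen.
#' @param method "exemplar" or "nj".
#' @param t distance threshold (exemplar method only).
#' @param tree optional precomputed NJ tree over references + queries
#'   (built from `m` when absent and `method = "nj"`).
#' @param complex_map named list mapping historic labels to the truth
#'   labels they lumped (used to recognise members of known complexes);
#'   default: the `complex_map` carried by `tax`.
#' @return list of class `DiscoveryTable`: `per_query` (query, status,
#'   outcome, assigned, category), `counts`, `n_queries`, `success_pct`
#'   (percentage in the three correct categories).
#' @export
discovery_assessment <- function(m, tax, method = c("exemplar", "nj"),
                                 t = 0.02, tree = NULL, complex_map = NULL) {
  method <- match.arg(method)
  status <- tax$discovery_status_of
  if (!length(status)) stop("taxonomy carries no discovery status")
  queries <- names(status)[status %in% c("new_taxon", "new_form_of_existing")]
  queries <- intersect(m$ids, queries)
  if (!length(queries)) stop("no queries with a new discovery status")
  refs <- setdiff(m$ids, queries)
  if (is.null(complex_map)) complex_map <- tax$complex_map
  lumped <- unique(unlist(complex_map[lengths(complex_map) >= 2L]))
  if (method == "exemplar") {
    ex <- tax$exemplar_of[names(tax$exemplar_of) %in%
                            unique(unname(tax$label_of[refs]))]
    ex <- ex[unname(ex) %in% refs]
    if (!length(ex)) stop("no exemplars among the reference specimens")
    res <- do.call(rbind, lapply(queries, distance_to_exemplar, m = m,
                                 tax = tax, t = t, exemplars = unname(ex)))
  } else {
    if (is.null(tree)) tree <- neighbor_joining(m)
    ref_tax <- tax
    ref_tax$exemplar_of <- tax$exemplar_of[unname(tax$exemplar_of) %in% refs]
    if (!length(ref_tax$exemplar_of))
      stop("no exemplars among the reference specimens")
    res <- nj_identify(tree, ref_tax, queries = queries)
  }
  cat_of <- character(nrow(res))
  for (i in seq_len(nrow(res))) {
    q <- res$query_id[i]
    st <- status[[q]]
    tl <- unname(tax$label_of[q])
    flagged <- identical(res$outcome[i], "no_match") ||
      (method == "nj" && identical(res$outcome[i], "ambiguous"))
    cat_of[i] <- if (flagged) {
      if (st == "new_form_of_existing") "incorrectly_flagged_new"
      else if (tl %in% lumped) "correctly_flagged_part_of_complex"
      else "correctly_flagged_new"
    } else {
      if (st == "new_form_of_existing") "correctly_grouped_existing"
      else "incorrectly_lumped"
    }
  }
  per_query <- data.frame(query_id = res$query_id, status = status[res$query_id],
                          outcome = res$outcome, assigned = res$assigned,
                          category = cat_of, row.names = NULL)
  counts <- table(factor(cat_of, levels = DISCOVERY_CATEGORIES))
  structure(list(per_query = per_query, counts = counts,
                 n_queries = nrow(per_query),
                 success_pct = 100 * sum(counts[1:3]) / nrow(per_query),
                 method = method, threshold = if (method == "exemplar") t
                 else NA_real_),
            class = "DiscoveryTable")
}

#' @export
print.DiscoveryTable <- function(x, ...) {
  cat("Species discovery (", x$method, "): ", x$n_queries, " queries, ",
      sprintf("%.0f%%", x$success_pct), " correct\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Run the full retrospective barcoding pipeline
#'
#' QC -> distances -> gap analysis -> NJ tree -> identification sweep ->
#' truth scoring, with an optional output directory receiving TSV tables,
#' a newick tree and a run manifest.
#'
#' @param set a `SequenceSet` with taxonomies attached (see
#'   [merge_dataset()]).
#' @param eval_scheme name of the taxonomy the identification runs under.
#' @param truth_scheme name of the truth taxonomy (default: same as
#'   `eval_scheme`, i.e. self-consistency scoring).
#' @param thresholds distance thresholds for the sweep (subs/site).
#' @param methods identification methods for the sweep.
#' @param abgd an [abgd_config()].
#' @param bootstrap_reps NJ bootstrap replicates (0 = plain NJ tree).
#' @param seed seed for the bootstrap.
#' @param out_dir optional directory for TSV/newick outputs and manifest.
#' @return list with `qc`, `matrix`, `pools`, `overlap_total`,
#'   `overlap_90`, `local_gaps`, `threshold_10x`, `abgd`, `tree`,
#'   `summary` (sweep table).
#' @export
run_pipeline <- function(set, eval_scheme, truth_scheme = eval_scheme,
                         thresholds = c(0.02, 0.04, 0.06, 0.08, 0.10),
                         methods = c("nj", "best_match", "best_close_match",
                                     "all_species_barcodes", "exemplar"),
                         abgd = abgd_config(), bootstrap_reps = 0, seed = 1,
                         out_dir = NULL) {
  stopifnot(inherits(set, "SequenceSet"))
  eval_tax <- set$taxonomies[[eval_scheme]]
  truth_tax <- set$taxonomies[[truth_scheme]]
  if (is.null(eval_tax) || is.null(truth_tax))
    stop("scheme not found among the set's taxonomies")
  qc <- screen_stop_codons(set)
  if (any(qc$has_internal_stop))
    warning(sum(qc$has_internal_stop),
            " sequence(s) contain internal stop codons")
  m <- build_matrix(set)
  ids <- intersect(m$ids, names(eval_tax$label_of))
  if (length(ids) < length(m$ids))
    message(length(m$ids) - length(ids), " specimen(s) not labelled in '",
            eval_scheme, "' excluded from that scheme's run")
  m_eval <- if (length(ids) < length(m$ids)) subset_matrix(m, ids) else m
  pools <- pool_distances(m_eval, eval_tax)
  overlap_total <- overlap_report(pools, 0)
  overlap_90 <- overlap_report(pools, 0.05)
  local_gaps <- local_gap_table(pools)
  thr10 <- threshold_10x(pools)
  abgd_res <- abgd_partition(m_eval, abgd)
  tree <- if (bootstrap_reps > 0) {
    bt <- bootstrap_support(set, n_reps = bootstrap_reps, seed = seed)
    bt$tree
  } else neighbor_joining(m_eval)
  summary <- threshold_sweep(m_eval, eval_tax, truth_tax, methods = methods,
                             thresholds = thresholds, tree = tree)
  out <- list(qc = qc, matrix = m_eval, pools = pools,
              overlap_total = overlap_total, overlap_90 = overlap_90,
              local_gaps = local_gaps, threshold_10x = thr10,
              abgd = abgd_res, tree = tree, summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) utils::write.table(x, file.path(out_dir, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)
    w(qc, "qc_stop_codons.tsv")
    w(local_gaps, "local_gaps.tsv")
    w(summary, "identification_summary.tsv")
    w(data.frame(statistic = c("overlap_total_lower", "overlap_total_upper",
                               "overlap_total_width", "overlap_total_pct_obs",
                               "overlap_90_lower", "overlap_90_upper",
                               "overlap_90_width", "overlap_90_pct_obs",
                               "threshold_10x", "abgd_consensus_threshold"),
                 value = c(overlap_total$lower, overlap_total$upper,
                           overlap_total$width, overlap_total$pct_observations,
                           overlap_90$lower, overlap_90$upper,
                           overlap_90$width, overlap_90$pct_observations,
                           thr10, abgd_res$consensus_threshold)),
      "gap_statistics.tsv")
    write_newick(tree, file.path(out_dir, "nj_tree.nwk"))
    writeLines(c(paste("package_version:",
                       as.character(utils::packageVersion("retrobarcode"))),
                 paste("r_version:", R.version.string),
                 paste("seed:", seed),
                 paste("eval_scheme:", eval_scheme),
                 paste("truth_scheme:", truth_scheme),
                 paste("thresholds:", paste(thresholds, collapse = ",")),
                 paste("methods:", paste(methods, collapse = ",")),
                 paste("n_specimens:", length(m_eval$ids)),
                 paste("timestamp:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
               file.path(out_dir, "run_manifest.txt"))
  }
  out
}
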