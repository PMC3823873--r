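# Specimen identification methods. All matching methods evaluate each
# query against the reference set with the query's own record removed
# (leave-one-out). Distance ties at the decision boundary (d == t) count
# as within the threshold; ties for the nearest reference are resolved at
# a 1e-12 relative tolerance.

.id_result <- function(query_id, method, threshold, assigned, outcome,
                       nearest_id = NA_character_, nearest_distance = NA_real_,
                       note = NA_character_) {
  data.frame(query_id = query_id, method = method,
             threshold = if (is.null(threshold)) NA_real_ else threshold,
             assigned = if (is.null(assigned)) NA_character_ else assigned,
             outcome = outcome, nearest_id = nearest_id,
             nearest_distance = nearest_distance, note = note,
             row.names = NULL)
}

.query_label <- function(q, tax) {
  lab <- tax$label_of[q]
  if (is.na(lab)) stop("query ", q, " is not labelled in scheme '",
                       tax$scheme_name, "'")
  unname(lab)
}

.ref_ids <- function(q, m, tax, refs) {
  if (is.null(refs)) refs <- m$ids
  refs <- setdiff(refs, q)               # leave-one-out
  if (!length(refs)) stop("no references left for query ", q)
  refs
}

#' Best Match identification
#'
#' Assigns the query to the species of its nearest reference(s). Exact
#' ties at the minimum spanning more than one species are ambiguous.
#'
#' @param q query specimen id.
#' @param m a `DistanceMatrix` containing the query and references.
#' @param tax `TaxonomyMap` used both to label references and to judge
#'   the outcome.
#' @param refs reference ids (default: all matrix ids); the query itself
#'   is always excluded.
#' @return one-row data.frame (see package results schema).
#' @export
best_match <- function(q, m, tax, refs = NULL) {
  refs <- .ref_ids(q, m, tax, refs)
  lab_q <- .query_label(q, tax)
  dv <- m$d[q, refs]
  dmin <- min(dv)
  near <- refs[dv <= dmin + 1e-12 * max(1, dmin)]
  spp <- unique(unname(tax$label_of[near]))
  if (length(spp) > 1L)
    return(.id_result(q, "best_match", NULL, NULL, "ambiguous",
                      near[1L], dmin, paste(spp, collapse = "|")))
  outcome <- if (spp == lab_q) "success" else "misidentified"
  .id_result(q, "best_match", NULL, spp, outcome, near[1L], dmin)
}

#' Best Close Match identification
#'
#' As Best Match, but the nearest reference is consulted only if it lies
#' within the threshold; otherwise the query has no match.
#'
#' @inheritParams best_match
#' @param t distance threshold (substitutions/site), > 0.
#' @export
best_close_match <- function(q, m, tax, t, refs = NULL) {
  stopifnot(t > 0)
  refs <- .ref_ids(q, m, tax, refs)
  dmin <- min(m$d[q, refs])
  if (dmin > t)
    return(.id_result(q, "best_close_match", t, NULL, "no_match",
                      refs[which.min(m$d[q, refs])], dmin))
  res <- best_match(q, m, tax, refs)
  res$method <- "best_close_match"
  res$threshold <- t
  res
}

#' All Species Barcodes identification
#'
#' Considers every reference within the threshold: all conspecific with
#' the query is a success, several species is ambiguous, a single wrong
#' species is a misidentification, none within threshold is no match.
#'
#' @inheritParams best_close_match
#' @export
all_species_barcodes <- function(q, m, tax, t, refs = NULL) {
  stopifnot(t > 0)
  refs <- .ref_ids(q, m, tax, refs)
  lab_q <- .query_label(q, tax)
  dv <- m$d[q, refs]
  within <- refs[dv <= t]
  nearest <- refs[which.min(dv)]
  if (!length(within))
    return(.id_result(q, "all_species_barcodes", t, NULL, "no_match",
                      nearest, min(dv)))
  spp <- unique(unname(tax$label_of[within]))
  if (length(spp) > 1L)
    return(.id_result(q, "all_species_barcodes", t, NULL, "ambiguous",
                      nearest, min(dv), paste(sort(spp), collapse = "|")))
  outcome <- if (spp == lab_q) "success" else "misidentified"
  .id_result(q, "all_species_barcodes", t, spp, outcome, nearest, min(dv))
}

#' Distance to Species Exemplar identification
#'
#' The query is compared to the designated exemplar sequences only. A
#' conspecific nearest exemplar within the threshold is a success, a
#' heterospecific one a misidentification, and a nearest exemplar beyond
#' the threshold leaves the query unmatched (candidate new species).
#'
#' @inheritParams best_close_match
#' @param tax `TaxonomyMap` whose `exemplar_of` designates one reference
#'   per species.
#' @param exemplars optional subset of exemplar specimen ids to use as
#'   references (default: all of `tax$exemplar_of`).
#' @export
distance_to_exemplar <- function(q, m, tax, t, exemplars = NULL) {
  stopifnot(t > 0)
  if (is.null(exemplars)) exemplars <- unname(tax$exemplar_of)
  if (!length(exemplars)) stop("no exemplars designated in scheme '",
                               tax$scheme_name, "'")
  refs <- setdiff(exemplars, q)
  if (!length(refs)) stop("no exemplar references left for query ", q)
  lab_q <- .query_label(q, tax)
  dv <- m$d[q, refs]
  e <- refs[which.min(dv)]
  d <- min(dv)
  if (d > t)
    return(.id_result(q, "exemplar", t, NULL, "no_match", e, d))
  sp <- unname(tax$label_of[e])
  outcome <- if (sp == lab_q) "success" else "misidentified"
  .id_result(q, "exemplar", t, sp, outcome, e, d)
}

# ---- NJ tree-based identification ------------------------------------------

# All bipartition sides of an unrooted tree as a logical matrix
# (rows = sides from internal nodes plus singleton tips; cols = tips).
.split_matrix <- function(tree) {
  n <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  M <- matrix(FALSE, length(pp) + n, n)
  for (i in seq_along(pp)) M[i, pp[[i]]] <- TRUE
  for (i in seq_len(n)) M[length(pp) + i, i] <- TRUE
  colnames(M) <- tree$tip.label
  M
}

#' Tree-based identification against exemplar sequences
#'
#' For each query the smallest bipartition side of the NJ tree containing
#' the query and at least one exemplar is examined. A single exemplar
#' species that matches the query's label is a success; several exemplar
#' species entering together is ambiguous. A single non-matching exemplar
#' species is a misidentification when the query is embedded among that
#' species' specimens, but is flagged as an ambiguous new-species
#' candidate when the query belongs to an exemplar-free clade of other
#' specimens none of which carry that species' label.
#'
#' @param tree a `phylo` (or `BootstrapTree`) whose tips are specimens.
#' @param tax `TaxonomyMap` with exemplars designated; every tip must be
#'   labelled.
#' @param queries specimen ids to identify (default: all non-exemplar
#'   tips).
#' @return data.frame of per-query results; new-species candidates carry
#'   `note == "new_candidate"`.
#' @export
nj_identify <- function(tree, tax, queries = NULL) {
  if (inherits(tree, "BootstrapTree")) tree <- tree$tree
  tips <- tree$tip.label
  exemplars <- unname(tax$exemplar_of)
  if (!length(exemplars)) stop("no exemplars designated in scheme '",
                               tax$scheme_name, "'")
  missing <- setdiff(exemplars, tips)
  if (length(missing)) stop("exemplar(s) absent from tree: ",
                            paste(missing, collapse = ", "))
  if (is.null(queries)) queries <- setdiff(tips, exemplars)
  lab <- tax$label_of[tips]
  if (any(is.na(lab))) stop("tip(s) unlabeled in scheme '", tax$scheme_name,
                            "': ", paste(tips[is.na(lab)], collapse = ", "))
  is_ex <- tips %in% exemplars
  ex_species <- stats::setNames(names(tax$exemplar_of), tax$exemplar_of)
  M <- .split_matrix(tree)
  n <- length(tips)
  rs <- rowSums(M)
  ex_in <- as.vector(M %*% is_ex)
  total_ex <- sum(is_ex)
  out <- vector("list", length(queries))
  for (k in seq_along(queries)) {
    q <- queries[k]
    qi <- match(q, tips)
    if (is.na(qi)) stop("query ", q, " is not a tip of the tree")
    has_q <- M[, qi]
    size <- ifelse(has_q, rs, n - rs)
    nex <- ifelse(has_q, ex_in, total_ex - ex_in)
    # smallest side containing the query and >= 1 exemplar
    cand <- which(nex >= 1L)
    smin <- min(size[cand])
    minimal <- cand[size[cand] == smin]
    in_side <- function(i) if (has_q[i]) which(M[i, ]) else which(!M[i, ])
    ex_tips <- unique(unlist(lapply(minimal, function(i) {
      s <- in_side(i); s[is_ex[s]]
    })))
    species <- sort(unique(unname(ex_species[tips[ex_tips]])))
    lab_q <- unname(lab[qi])
    # query-only neighbourhood: largest exemplar-free side containing q
    free <- which(nex == 0L)
    D <- if (length(free)) in_side(free[which.max(size[free])]) else qi
    others <- setdiff(D, qi)
    embedded <- length(others) > 0L && any(lab[others] %in% species)
    if (length(species) > 1L) {
      # several exemplar species enter together; when the query sits in
      # an exemplar-free clade carrying none of their labels (nor its
      # own conspecific exemplar) it is additionally a new-species
      # candidate
      note <- if (!lab_q %in% species && !embedded && length(others))
        "new_candidate" else paste(species, collapse = "|")
      out[[k]] <- .id_result(q, "nj", NULL, NULL, "ambiguous", note = note)
      next
    }
    X <- species
    if (X == lab_q) {
      out[[k]] <- .id_result(q, "nj", NULL, X, "success")
      next
    }
    if (!length(others) || embedded) {
      out[[k]] <- .id_result(q, "nj", NULL, X, "misidentified")
    } else {
      out[[k]] <- .id_result(q, "nj", NULL, NULL, "ambiguous",
                             note = "new_candidate")
    }
  }
  do.call(rbind, out)
}

#' Run one or more identification methods over a set of queries
#'
#' @param m a `DistanceMatrix`.
#' @param tax evaluation `TaxonomyMap`.
#' @param methods subset of `c("best_match", "best_close_match",
#'   "all_species_barcodes", "exemplar", "nj")`.
#' @param threshold distance threshold for threshold-bearing methods
#'   (substitutions/site).
#' @param queries query ids (default: all matrix ids; for the exemplar
#'   method exemplar records are still scored, against the other
#'   exemplars, unless `score_exemplar_queries = FALSE`).
#' @param refs reference ids for the matching methods (default all).
#' @param tree NJ tree (required when "nj" is among the methods).
#' @param score_exemplar_queries whether exemplar specimens are scored as
#'   queries under the exemplar method.
#' @return data.frame of per-query, per-method results.
#' @export
identify_specimens <- function(m, tax, methods, threshold = NULL,
                               queries = NULL, refs = NULL, tree = NULL,
                               score_exemplar_queries = TRUE) {
  if (is.null(queries)) queries <- m$ids
  res <- list()
  for (meth in methods) {
    rows <- switch(meth,
      best_match = lapply(queries, best_match, m = m, tax = tax, refs = refs),
      best_close_match = lapply(queries, best_close_match, m = m, tax = tax,
                                t = threshold, refs = refs),
      all_species_barcodes = lapply(queries, all_species_barcodes, m = m,
                                    tax = tax, t = threshold, refs = refs),
      exemplar = {
        qs <- if (score_exemplar_queries) queries
              else setdiff(queries, unname(tax$exemplar_of))
        lapply(qs, distance_to_exemplar, m = m, tax = tax, t = threshold)
      },
      nj = {
        if (is.null(tree)) stop("the nj method needs a tree")
        list(nj_identify(tree, tax,
                         queries = setdiff(queries, unname(tax$exemplar_of))))
      },
      stop("unknown method: ", meth))
    res <- c(res, rows)
  }
  do.call(rbind, res)
}
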