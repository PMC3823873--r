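# Barcoding-gap analytics: intra/inter distance pools, global overlap,
# per-species local gaps, candidate thresholds (ABGD-style scan and the
# 10x mean-intraspecific rule), and the between-taxonomy ANOVA.

#' Partition a distance matrix into intra- and inter-specific pools
#'
#' A pair is intraspecific iff both specimens carry the same label under
#' the given scheme. Singleton species contribute no intraspecific
#' distances but are present in the nearest-neighbour table.
#'
#' @param m a `DistanceMatrix`.
#' @param tax a `TaxonomyMap` labelling every id of `m`. Ids missing from
#'   the scheme are an error; subset the matrix first if a scheme covers
#'   only part of the data (see [subset_matrix()]).
#' @return object of class `DistancePools`: `intra_by_species` (named list
#'   of numeric vectors), `intra_pooled`, `inter_pooled`, `max_intra`
#'   (named, species with >= 2 specimens), `nn_dist` (named, all species
#'   when >= 2 species exist), `n_specimens` (named integer).
#' @export
pool_distances <- function(m, tax) {
  stopifnot(inherits(m, "DistanceMatrix"), inherits(tax, "TaxonomyMap"))
  lab <- tax$label_of[m$ids]
  if (any(is.na(lab)))
    stop("unlabeled specimen(s) in scheme '", tax$scheme_name, "': ",
         paste(utils::head(m$ids[is.na(lab)], 5L), collapse = ", "))
  ut <- upper.tri(m$d)
  same <- outer(lab, lab, "==")
  intra_pooled <- m$d[ut & same]
  inter_pooled <- m$d[ut & !same]
  species <- sort(unique(unname(lab)))
  intra_by_species <- list()
  max_intra <- numeric(); nn_dist <- numeric()
  for (sp in species) {
    idx <- which(lab == sp)
    if (length(idx) >= 2L) {
      sub <- m$d[idx, idx, drop = FALSE]
      v <- sub[upper.tri(sub)]
      intra_by_species[[sp]] <- v
      max_intra[sp] <- max(v)
    }
    if (length(idx) < length(lab))
      nn_dist[sp] <- min(m$d[idx, -idx, drop = FALSE])
  }
  structure(list(intra_by_species = intra_by_species,
                 intra_pooled = intra_pooled, inter_pooled = inter_pooled,
                 max_intra = max_intra, nn_dist = nn_dist,
                 n_specimens = vapply(split(seq_along(lab), lab), length, 1L)),
            class = "DistancePools")
}

#' Restrict a distance matrix to a subset of specimens
#'
#' @param m a `DistanceMatrix`.
#' @param ids specimen ids to keep.
#' @return a `DistanceMatrix` over `ids`.
#' @export
subset_matrix <- function(m, ids) {
  stopifnot(inherits(m, "DistanceMatrix"))
  missing <- setdiff(ids, m$ids)
  if (length(missing)) stop("ids not in matrix: ", paste(missing, collapse = ", "))
  structure(list(ids = ids, d = m$d[ids, ids, drop = FALSE],
                 n_sites = m$n_sites[ids, ids, drop = FALSE]),
            class = "DistanceMatrix")
}

#' Global barcoding-gap overlap between intra- and inter-specific distances
#'
#' The overlap interval runs from the smallest interspecific to the
#' largest intraspecific distance, optionally after trimming extreme
#' tails by count: the largest `ceiling(trim_fraction * n_intra)`
#' intraspecific values and the smallest `ceiling(trim_fraction *
#' n_inter)` interspecific values are discarded (the "90% overlap" uses
#' `trim_fraction = 0.05`). `pct_observations` is the percentage of all
#' pooled distances (intra and inter combined) lying in the closed
#' interval; a degenerate interval (upper <= lower) means no overlap.
#'
#' @param pools a `DistancePools`.
#' @param trim_fraction fraction of each tail to discard (0 or 0.05).
#' @return list with `lower`, `upper`, `width`, `pct_observations`,
#'   `trim_fraction`.
#' @export
overlap_report <- function(pools, trim_fraction = 0) {
  intra <- pools$intra_pooled; inter <- pools$inter_pooled
  if (!length(intra) || !length(inter))
    stop("both intra- and inter-specific pools must be non-empty")
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5)
  k_intra <- if (trim_fraction > 0) ceiling(trim_fraction * length(intra)) else 0L
  k_inter <- if (trim_fraction > 0) ceiling(trim_fraction * length(inter)) else 0L
  if (k_intra >= length(intra) || k_inter >= length(inter))
    stop("trim discards an entire pool")
  upper <- sort(intra, decreasing = TRUE)[k_intra + 1L]
  lower <- sort(inter)[k_inter + 1L]
  width <- max(0, upper - lower)
  pooled <- c(intra, inter)
  pct <- if (width > 0) 100 * mean(pooled >= lower & pooled <= upper) else 0
  list(lower = lower, upper = upper, width = width,
       pct_observations = pct, trim_fraction = trim_fraction)
}

#' Per-species local barcoding gap table
#'
#' A species has a local gap when its nearest-neighbour distance exceeds
#' its maximum intraspecific distance. Singletons have `max_intra = 0`
#' and always show a gap.
#'
#' @param pools a `DistancePools` built from >= 2 species.
#' @return data.frame with `species`, `n`, `max_intra`, `nn`, `status`
#'   (`gap_present`, `absent_below`, `absent_on_line`); the counts of each
#'   status are attached as attribute `status_counts`.
#' @export
local_gap_table <- function(pools) {
  species <- names(pools$nn_dist)
  if (length(species) < 2L) stop("need >= 2 species for local gap analysis")
  mi <- ifelse(species %in% names(pools$max_intra),
               pools$max_intra[species], 0)
  nn <- pools$nn_dist[species]
  status <- ifelse(nn > mi, "gap_present",
                   ifelse(nn == mi, "absent_on_line", "absent_below"))
  out <- data.frame(species = species, n = pools$n_specimens[species],
                    max_intra = unname(mi), nn = unname(nn),
                    status = unname(status), row.names = NULL)
  attr(out, "status_counts") <- table(factor(out$status, levels =
    c("gap_present", "absent_below", "absent_on_line")))
  out
}

#' Threshold from the 10x mean-intraspecific-divergence rule
#'
#' @param pools a `DistancePools` with a non-empty intraspecific pool.
#' @return 10 times the mean pooled intraspecific distance (subs/site).
#' @export
threshold_10x <- function(pools) {
  if (!length(pools$intra_pooled)) stop("empty intraspecific pool")
  10 * mean(pools$intra_pooled)
}

#' ABGD-style configuration
#'
#' @param p_min,p_max bounds of the prior intraspecific divergence grid.
#' @param steps number of log-spaced priors.
#' @param X relative gap width: a gap qualifies when the spacing between
#'   consecutive sorted distances exceeds `X * prior`.
#' @return list of class `AbgdConfig`.
#' @export
abgd_config <- function(p_min = 0.001, p_max = 0.1, steps = 20, X = 1.5) {
  stopifnot(p_min > 0, p_min < p_max, steps >= 1, X > 0)
  structure(list(p_min = p_min, p_max = p_max, steps = as.integer(steps), X = X),
            class = "AbgdConfig")
}

# first spacing between consecutive sorted distances both above the
# prior that is wider than X * prior; NA when none qualifies
.first_gap_threshold <- function(dists, prior, X) {
  s <- sort(dists)
  if (length(s) < 2L) return(NA_real_)
  gaps <- diff(s)
  ok <- which(s[-length(s)] > prior & gaps > X * prior)
  if (!length(ok)) return(NA_real_)
  i <- ok[1L]
  (s[i] + s[i + 1L]) / 2
}

.single_linkage_groups <- function(d, ids, threshold) {
  n <- length(ids)
  comp <- seq_len(n)
  adj <- d < threshold
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (length(nb)) {
        mc <- min(comp[c(i, nb)])
        if (any(comp[c(i, nb)] != mc)) { comp[c(i, nb)] <- mc; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  split(ids, comp)
}

.abgd_recurse <- function(d, ids, prior, X, depth = 0L) {
  if (length(ids) < 3L || depth > 20L) return(list(ids))
  sub <- d[ids, ids, drop = FALSE]
  thr <- .first_gap_threshold(sub[upper.tri(sub)], prior, X)
  if (is.na(thr)) return(list(ids))
  groups <- .single_linkage_groups(sub, ids, thr)
  if (length(groups) == 1L) return(list(ids))
  out <- list()
  for (g in groups) out <- c(out, .abgd_recurse(d, g, prior, X, depth + 1L))
  out
}

#' ABGD-style recursive barcode-gap partitioning
#'
#' For each prior on a log-spaced grid, scans the sorted pairwise
#' distances for the first spacing above the prior wider than `X * prior`,
#' splits the specimens by single linkage at the spacing's midpoint, and
#' recurses within groups. The consensus is taken over the priors whose
#' partition has the modal group count.
#'
#' @param m a `DistanceMatrix` over >= 3 specimens.
#' @param cfg an [abgd_config()].
#' @return list of class `AbgdResult`: `per_prior` (data.frame with
#'   `prior`, `threshold`, `n_groups`), `partitions` (list of partitions,
#'   one per prior), `modal_n_groups`, `consensus_interval` (range of
#'   initial thresholds among modal priors), `consensus_threshold`
#'   (midpoint of that range), `no_gap` (TRUE when no prior found a gap).
#' @export
abgd_partition <- function(m, cfg = abgd_config()) {
  stopifnot(inherits(m, "DistanceMatrix"))
  if (length(m$ids) < 3L) stop("need >= 3 specimens")
  priors <- exp(seq(log(cfg$p_min), log(cfg$p_max), length.out = cfg$steps))
  dv <- m$d[upper.tri(m$d)]
  thresholds <- vapply(priors, function(p) .first_gap_threshold(dv, p, cfg$X), 0)
  partitions <- vector("list", length(priors))
  n_groups <- integer(length(priors))
  for (i in seq_along(priors)) {
    if (is.na(thresholds[i])) {
      partitions[[i]] <- list(m$ids); n_groups[i] <- 1L
    } else {
      partitions[[i]] <- .abgd_recurse(m$d, m$ids, priors[i], cfg$X)
      n_groups[i] <- length(partitions[[i]])
    }
  }
  no_gap <- all(is.na(thresholds))
  # the consensus is taken over priors that found a gap; priors whose
  # scan failed carry no threshold and only matter for the no-gap flag
  found <- !is.na(thresholds)
  modal <- if (no_gap) 1L else {
    counts <- table(n_groups[found])
    as.integer(names(counts)[which.max(counts)])
  }
  sel <- which(n_groups == modal & found)
  ci <- if (length(sel)) range(thresholds[sel]) else c(NA_real_, NA_real_)
  structure(list(per_prior = data.frame(prior = priors, threshold = thresholds,
                                        n_groups = n_groups),
                 partitions = partitions, modal_n_groups = modal,
                 consensus_interval = ci,
                 consensus_threshold = mean(ci), no_gap = no_gap),
            class = "AbgdResult")
}

#' @export
print.AbgdResult <- function(x, ...) {
  if (x$no_gap) cat("ABGD: no qualifying gap at any prior (single group)\n")
  else cat("ABGD: modal partition has", x$modal_n_groups, "groups;",
           "consensus threshold", sprintf("%.4f", x$consensus_threshold),
           sprintf("(range %.4f-%.4f)", x$consensus_interval[1L],
                   x$consensus_interval[2L]), "\n")
  invisible(x)
}

#' One-way ANOVA comparing species-level intraspecific divergences
#'
#' Compares per-species summary values (e.g. mean intraspecific K2P
#' distance) between two taxonomy schemes.
#'
#' @param groupA,groupB numeric vectors of per-species values (>= 2 each).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
anova_intraspecific <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs >= 2 species-level values")
  val <- c(groupA, groupB)
  grp <- factor(rep(c("A", "B"), c(length(groupA), length(groupB))))
  fit <- stats::anova(stats::lm(val ~ grp))
  list(F = fit[["F value"]][1L], df1 = fit[["Df"]][1L], df2 = fit[["Df"]][2L],
       p = fit[["Pr(>F)"]][1L])
}

#' Per-species mean intraspecific distances
#'
#' Convenience extractor feeding [anova_intraspecific()]: species with a
#' single specimen are excluded (they have no intraspecific distances).
#'
#' @param pools a `DistancePools`.
#' @param fun summary function, default `mean` (use `max` for maxima).
#' @return named numeric vector, one value per multi-specimen species.
#' @export
species_intra_means <- function(pools, fun = mean) {
  vapply(pools$intra_by_species, fun, 0)
}
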