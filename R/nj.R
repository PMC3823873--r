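# Neighbour-joining with a deterministic tie rule, plus nonparametric
# bootstrap over alignment sites. Trees are ape "phylo" objects so the
# usual newick tooling applies.

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Q criterion. Ties in Q are broken by
#' the lexicographically smallest id pair, where a cluster is named by
#' the smallest leaf id it contains, so the result is deterministic.
#' Negative branch lengths are clamped to zero with the deficit moved to
#' the sister branch of the join.
#'
#' @param m a `DistanceMatrix` (or plain symmetric matrix with dimnames)
#'   over >= 3 specimens.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(m) {
  d <- if (inherits(m, "DistanceMatrix")) m$d else as.matrix(m)
  ids <- rownames(d)
  n <- length(ids)
  if (n < 3L) stop("need >= 3 specimens for neighbour joining")
  n_tip <- n
  node_ids <- seq_len(n)                 # phylo node numbers of active clusters
  labels <- ids                          # lexicographic cluster names
  next_node <- 2L * n_tip - 2L           # internal numbering n+1 .. 2n-2, root last
  edges <- matrix(0L, 0L, 2L); edge_len <- numeric(0)
  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    edge_len <<- c(edge_len, max(0, len))
  }
  internal_next <- n_tip + 2L            # reserve n_tip+1 for the final node
  active <- seq_len(n)
  D <- d
  while (length(active) > 3L) {
    na <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (na - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      p <- sort(c(labels[active[ij[1L]]], labels[active[ij[2L]]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    ai <- active[i]; aj <- active[j]
    li <- 0.5 * Dm[i, j] + (r[i] - r[j]) / (2 * (na - 2))
    lj <- Dm[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new <- internal_next; internal_next <- internal_next + 1L
    add_edge(new, node_ids[ai], li)
    add_edge(new, node_ids[aj], lj)
    # distances from the new cluster to the others
    others <- setdiff(active, c(ai, aj))
    newd <- 0.5 * (D[ai, others] + D[aj, others] - D[ai, aj])
    D <- rbind(cbind(D, 0), 0)
    k <- nrow(D)
    D[k, others] <- newd; D[others, k] <- newd
    node_ids <- c(node_ids, new)
    labels <- c(labels, min(labels[c(ai, aj)]))
    active <- c(others, k)
  }
  # final three clusters join at one node (unrooted trifurcation)
  a <- active[1L]; b <- active[2L]; c3 <- active[3L]
  la <- 0.5 * (D[a, b] + D[a, c3] - D[b, c3])
  lb <- 0.5 * (D[a, b] + D[b, c3] - D[a, c3])
  lc <- 0.5 * (D[a, c3] + D[b, c3] - D[a, b])
  root <- n_tip + 1L
  ord <- order(labels[c(a, b, c3)])
  lens <- c(la, lb, lc)[ord]
  nodes <- node_ids[c(a, b, c3)][ord]
  for (k in 1:3) add_edge(root, nodes[k], lens[k])
  tr <- list(edge = edges, edge.length = edge_len, tip.label = ids,
             Nnode = internal_next - n_tip - 1L)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Neighbour-joining with bootstrap support over alignment sites
#'
#' Alignment columns are resampled with replacement; each replicate gets
#' its own K2P matrix and NJ tree. Support for each internal bipartition
#' of the original tree is the percentage of successful replicates
#' containing it. Replicates producing a saturated or non-comparable pair
#' are skipped and counted.
#'
#' @param set an aligned `SequenceSet`.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed; the run is reproducible given the seed.
#' @return list of class `BootstrapTree`: `tree` (phylo with node labels
#'   set to integer support percentages), `support` (numeric vector per
#'   internal node), `n_reps`, `n_used`, `n_skipped`.
#' @export
bootstrap_support <- function(set, n_reps = 100, seed = 1) {
  stopifnot(inherits(set, "SequenceSet"), set$aligned, n_reps >= 1)
  base_m <- build_matrix(set)
  tree <- neighbor_joining(base_m)
  L <- set$aligned_length
  rec_mat <- do.call(rbind, set$records)
  set.seed(seed)
  boots <- vector("list", n_reps)
  n_skipped <- 0L
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_set <- sequence_set(stats::setNames(
      lapply(seq_along(set$ids), function(i) rec_mat[i, cols]), set$ids))
    tr <- tryCatch(neighbor_joining(build_matrix(rep_set)),
                   error = function(e) NULL)
    if (is.null(tr)) n_skipped <- n_skipped + 1L else boots[[r]] <- tr
  }
  boots <- boots[!vapply(boots, is.null, TRUE)]
  if (n_skipped > 0L)
    message(n_skipped, " bootstrap replicate(s) skipped (undefined distances)")
  if (!length(boots)) stop("all bootstrap replicates failed")
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / length(boots)
  tree$node.label <- as.character(round(support))
  structure(list(tree = tree, support = support, n_reps = n_reps,
                 n_used = length(boots), n_skipped = n_skipped),
            class = "BootstrapTree")
}

#' @export
print.BootstrapTree <- function(x, ...) {
  cat("NJ tree with bootstrap support:", length(x$tree$tip.label), "tips;",
      x$n_used, "of", x$n_reps, "replicates used; median support",
      stats::median(x$support), "\n")
  invisible(x)
}

#' Write a tree (with any support labels) to a newick file
#'
#' @param tree a `phylo` or `BootstrapTree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "BootstrapTree")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}
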