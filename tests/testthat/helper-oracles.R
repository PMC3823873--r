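# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain site loops, exhaustive enumeration and
# closed forms.

# brute-force K2P: explicit per-site loop, no vectorisation
k2p_brute <- function(a, b) {
  a <- tolower(a); b <- tolower(b)
  bases <- c("a", "c", "g", "t")
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(a)) {
    if (a[i] %in% bases && b[i] %in% bases) {
      n <- n + 1L
      if (a[i] != b[i]) {
        pair <- sort(c(a[i], b[i]))
        if (identical(pair, c("a", "g")) || identical(pair, c("c", "t")))
          ts <- ts + 1L
        else tv <- tv + 1L
      }
    }
  }
  P <- ts / n; Q <- tv / n
  list(d = -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q),
       P = P, Q = Q, n_sites = n)
}

random_pair <- function(L = 120, p_sub = 0.05, p_gap = 0.05) {
  bases <- c("a", "c", "g", "t")
  a <- sample(bases, L, replace = TRUE)
  b <- a
  flip <- runif(L) < p_sub
  b[flip] <- sample(bases, sum(flip), replace = TRUE)
  b[runif(L) < p_gap] <- "-"
  a[runif(L) < p_gap] <- "-"
  list(a = a, b = b)
}

# enumeration oracle for the overlap report: sort, drop by count, count
# membership with a loop
overlap_brute <- function(intra, inter, trim) {
  ki <- if (trim > 0) ceiling(trim * length(intra)) else 0
  kj <- if (trim > 0) ceiling(trim * length(inter)) else 0
  si <- sort(intra); sj <- sort(inter)
  upper <- si[length(si) - ki]
  lower <- sj[kj + 1]
  width <- max(0, upper - lower)
  inside <- 0
  for (x in c(intra, inter)) if (x >= lower && x <= upper) inside <- inside + 1
  pct <- if (width > 0) 100 * inside / (length(intra) + length(inter)) else 0
  list(lower = lower, upper = upper, width = width, pct = pct)
}

# a random additive distance matrix from a random tree with positive
# branch lengths, plus the tree itself
random_additive <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) runif(k, 0.02, 0.3))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

as_dmat <- function(d) {
  structure(list(ids = rownames(d), d = d,
                 n_sites = matrix(100L, nrow(d), ncol(d),
                                  dimnames = dimnames(d))),
            class = "DistanceMatrix")
}

# tiny labelled dataset builder for the matching-method tests: specimens
# on a 1-D line; distances are absolute differences (a valid metric)
line_dataset <- function(pos, labels) {
  ids <- names(pos)
  d <- outer(pos, pos, function(x, y) abs(x - y))
  dimnames(d) <- list(ids, ids)
  list(m = as_dmat(d),
       tax = taxonomy_map("line", stats::setNames(labels, ids)))
}

# independent naive classifiers for the matching methods
naive_best_match <- function(q, d, lab) {
  refs <- setdiff(rownames(d), q)
  dv <- d[q, refs]
  near <- refs[abs(dv - min(dv)) <= 1e-12]
  spp <- unique(lab[near])
  if (length(spp) > 1) return("ambiguous")
  if (spp == lab[q]) "success" else "misidentified"
}
naive_bcm <- function(q, d, lab, t) {
  refs <- setdiff(rownames(d), q)
  if (min(d[q, refs]) > t) return("no_match")
  naive_best_match(q, d, lab)
}
naive_asb <- function(q, d, lab, t) {
  refs <- setdiff(rownames(d), q)
  within <- refs[d[q, refs] <= t]
  if (!length(within)) return("no_match")
  spp <- unique(lab[within])
  if (length(spp) > 1) return("ambiguous")
  if (spp == lab[q]) "success" else "misidentified"
}

canon_partition <- function(p)
  sort(unname(vapply(p, function(g) paste(sort(g), collapse = ","), "")))
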