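# Kimura 2-parameter distances with pairwise deletion.
#
# Only unambiguous A/C/G/T sites shared by both sequences are compared
# (gaps and IUPAC ambiguity codes are deleted pairwise). Transitions are
# A<->G and C<->T; every other mismatch is a transversion.

K2P_BASES <- c("a", "c", "g", "t")

.encode_bases <- function(chars) {
  # a=1, c=2, g=3, t=4, anything else (gap/ambiguity) = 0
  m <- match(chars, K2P_BASES)
  m[is.na(m)] <- 0L
  m
}

.k2p_from_counts <- function(ts, tv, n, ids = c("a", "b")) {
  if (n < 1L) stop("no comparable sites between ", ids[1L], " and ", ids[2L])
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("saturated pair: K2P distance undefined between ",
         ids[1L], " and ", ids[2L])
  list(d = -0.5 * log(w1) - 0.25 * log(w2), P = P, Q = Q, n_sites = as.integer(n))
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' @param a,b sequences: character vectors of bases, single strings, or
#'   specimen ids naming records of `set`.
#' @param set optional `SequenceSet` when `a` and `b` are specimen ids.
#' @return list with `d` (substitutions/site), `P` (transition
#'   proportion), `Q` (transversion proportion) and `n_sites` (comparable
#'   sites). Errors if no site is comparable or the pair is saturated
#'   (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`).
#' @export
k2p <- function(a, b, set = NULL) {
  ids <- c("a", "b")
  if (!is.null(set)) {
    ids <- c(a, b)
    a <- set$records[[a]]; b <- set$records[[b]]
    if (is.null(a) || is.null(b)) stop("unknown specimen id")
  }
  if (length(a) == 1L) a <- strsplit(a, "", fixed = TRUE)[[1L]]
  if (length(b) == 1L) b <- strsplit(b, "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("sequences have unequal aligned lengths")
  ea <- .encode_bases(tolower(a))
  eb <- .encode_bases(tolower(b))
  use <- ea > 0L & eb > 0L
  n <- sum(use)
  if (n < 1L) stop("no comparable sites between ", ids[1L], " and ", ids[2L])
  x <- ea[use]; y <- eb[use]
  diff <- x != y
  # purines code to odd (a=1, g=3), pyrimidines to even (c=2, t=4):
  # a mismatch within one parity class is a transition
  ts <- sum(diff & (x %% 2L) == (y %% 2L))
  tv <- sum(diff) - ts
  .k2p_from_counts(ts, tv, n, ids)
}

#' Build the full K2P distance matrix for an aligned set
#'
#' All unordered pairs are computed with pairwise deletion; any saturated
#' or non-comparable pair aborts the computation, naming the pair.
#'
#' @param set an aligned `SequenceSet` with >= 2 records.
#' @return object of class `DistanceMatrix`: list with `ids`, `d`
#'   (symmetric numeric matrix, zero diagonal) and `n_sites` (integer
#'   matrix of comparable-site counts).
#' @export
build_matrix <- function(set) {
  stopifnot(inherits(set, "SequenceSet"))
  if (!set$aligned) stop("sequences must be aligned (equal lengths)")
  n <- length(set$ids)
  if (n < 2L) stop("need >= 2 records for a distance matrix")
  enc <- vapply(set$records, .encode_bases, integer(set$aligned_length))
  enc <- t(enc)                                   # n x L, 0 = non-comparable
  # one-hot site indicators per base give pairwise counts by matrix products
  known <- (enc > 0L) * 1
  ia <- (enc == 1L) * 1; ic <- (enc == 2L) * 1
  ig <- (enc == 3L) * 1; it <- (enc == 4L) * 1
  n_comp <- known %*% t(known)
  same <- ia %*% t(ia) + ic %*% t(ic) + ig %*% t(ig) + it %*% t(it)
  pur <- ia + ig; pyr <- ic + it
  same_class <- pur %*% t(pur) + pyr %*% t(pyr)
  ts <- same_class - same                          # within-class mismatches
  tv <- n_comp - same_class                        # cross-class pairs
  bad <- which(n_comp < 1 & upper.tri(n_comp), arr.ind = TRUE)
  if (nrow(bad))
    stop("no comparable sites between ", set$ids[bad[1L, 1L]], " and ",
         set$ids[bad[1L, 2L]])
  P <- ts / n_comp
  Q <- tv / n_comp
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  sat <- which((w1 <= 0 | w2 <= 0) & upper.tri(w1), arr.ind = TRUE)
  if (nrow(sat))
    stop("saturated pair: K2P distance undefined between ",
         set$ids[sat[1L, 1L]], " and ", set$ids[sat[1L, 2L]])
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  diag(d) <- 0
  d <- (d + t(d)) / 2                              # enforce exact symmetry
  dimnames(d) <- list(set$ids, set$ids)
  storage.mode(n_comp) <- "integer"
  dimnames(n_comp) <- dimnames(d)
  structure(list(ids = set$ids, d = d, n_sites = n_comp),
            class = "DistanceMatrix")
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  off <- x$d[upper.tri(x$d)]
  cat("DistanceMatrix:", length(x$ids), "specimens; K2P range",
      sprintf("%.4f-%.4f", min(off), max(off)), "subs/site\n")
  invisible(x)
}

#' Write a distance matrix to disk
#'
#' @param m a `DistanceMatrix`.
#' @param path output path.
#' @param format "square" (TSV with header) or "lower" (lower-triangular
#'   CSV, MEGA-like).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("square", "lower")) {
  format <- match.arg(format)
  if (format == "square") {
    utils::write.table(m$d, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(m$ids)) {
      row <- if (i == 1L) m$ids[i]
             else paste(c(m$ids[i], formatC(m$d[i, seq_len(i - 1L)],
                                            format = "g", digits = 10)),
                        collapse = ",")
      writeLines(row, con)
    }
  }
  invisible(path)
}
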