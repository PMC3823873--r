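# IUPAC nucleotide codes (lower case) plus the gap character accepted in input.
IUPAC_CODES <- c("a", "c", "g", "t", "u", "r", "y", "s", "w", "k", "m",
                 "b", "d", "h", "v", "n", "-", "?")

#' Construct a sequence set
#'
#' A `SequenceSet` bundles aligned (or raw) nucleotide records with any
#' number of named taxonomy schemes. Records are stored as per-site
#' character vectors in lower case; the IUPAC alphabet plus `-` is enforced.
#'
#' @param sequences named list (or named character vector) of nucleotide
#'   sequences; names are specimen ids.
#' @param taxonomies named list of `TaxonomyMap` objects (optional).
#' @return an object of class `SequenceSet` with fields `records`, `ids`,
#'   `aligned` (TRUE when all sequences share one length), `aligned_length`
#'   and `taxonomies`.
#' @export
sequence_set <- function(sequences, taxonomies = list()) {
  if (length(sequences) == 0L) stop("a SequenceSet needs at least one record")
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) stop("every record needs a specimen id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate specimen id(s): ", paste(unique(dup), collapse = ", "))
  records <- lapply(sequences, function(s) {
    if (length(s) == 1L) s <- strsplit(s, "", fixed = TRUE)[[1L]]
    s <- tolower(as.character(s))
    if (length(s) == 0L) stop("empty sequence")
    bad <- setdiff(unique(s), IUPAC_CODES)
    if (length(bad)) stop("non-IUPAC character(s) in sequence: ", paste(bad, collapse = ", "))
    s
  })
  names(records) <- ids
  lens <- lengths(records)
  aligned <- length(unique(lens)) == 1L
  structure(list(records = records, ids = ids, aligned = aligned,
                 aligned_length = if (aligned) lens[[1L]] else NA_integer_,
                 taxonomies = taxonomies),
            class = "SequenceSet")
}

#' @export
print.SequenceSet <- function(x, ...) {
  cat("SequenceSet:", length(x$ids), "records;",
      if (x$aligned) paste0("aligned, ", x$aligned_length, " sites")
      else "unaligned (unequal lengths)", "\n")
  if (length(x$taxonomies))
    cat("taxonomy schemes:", paste(names(x$taxonomies), collapse = ", "), "\n")
  invisible(x)
}

#' Read aligned sequences from a FASTA file
#'
#' Ids are the header token before the first whitespace. Duplicate ids and
#' empty files are errors.
#'
#' @param path path to a FASTA file.
#' @return a `SequenceSet` (records only, no taxonomies).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(x) || length(x) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- lapply(as.character(x), function(s) s)
  names(seqs) <- ids
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate specimen id(s) in ", path, ": ",
                        paste(unique(dup), collapse = ", "))
  sequence_set(seqs)
}

#' Write a sequence set as FASTA
#'
#' @param set a `SequenceSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(set, path) {
  stopifnot(inherits(set, "SequenceSet"))
  lines <- character(2L * length(set$ids))
  lines[c(TRUE, FALSE)] <- paste0(">", set$ids)
  lines[c(FALSE, TRUE)] <- vapply(set$records, paste, "", collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a taxonomy map
#'
#' One taxonomy scheme: specimen labels, optional per-species exemplar
#' designations, optional discovery status and an optional lumping map
#' recording which labels of a finer scheme this scheme's labels span.
#'
#' @param scheme_name name of the scheme (e.g. "historic", "current").
#' @param label_of named character vector, specimen id -> species label.
#' @param exemplar_of named character vector, species label -> specimen id
#'   (at most one per species).
#' @param discovery_status_of named character vector, specimen id ->
#'   one of `known_historic`, `new_taxon`, `new_form_of_existing`.
#' @param complex_map named list, label in this scheme -> character vector
#'   of labels in a finer scheme that it lumps.
#' @return an object of class `TaxonomyMap`.
#' @export
taxonomy_map <- function(scheme_name, label_of, exemplar_of = character(),
                         discovery_status_of = character(),
                         complex_map = list()) {
  stopifnot(is.character(label_of), !is.null(names(label_of)))
  if (any(is.na(label_of) | !nzchar(label_of)))
    stop("scheme '", scheme_name, "': every specimen needs a non-empty label")
  if (length(exemplar_of)) {
    if (anyDuplicated(names(exemplar_of)))
      stop("scheme '", scheme_name, "': two exemplars designated for species ",
           names(exemplar_of)[duplicated(names(exemplar_of))][1L])
    unknown <- setdiff(exemplar_of, names(label_of))
    if (length(unknown))
      stop("scheme '", scheme_name, "': exemplar points to unknown specimen ",
           paste(unknown, collapse = ", "))
  }
  if (length(complex_map) && any(lengths(complex_map) == 0L))
    stop("complex_map values must be non-empty sets")
  structure(list(scheme_name = scheme_name, label_of = label_of,
                 exemplar_of = exemplar_of,
                 discovery_status_of = discovery_status_of,
                 complex_map = complex_map),
            class = "TaxonomyMap")
}

#' @export
print.TaxonomyMap <- function(x, ...) {
  cat("TaxonomyMap '", x$scheme_name, "': ", length(x$label_of),
      " specimens, ", length(unique(x$label_of)), " species, ",
      length(x$exemplar_of), " exemplars\n", sep = "")
  invisible(x)
}

#' Read specimen metadata from a tab-separated file
#'
#' The file must have a header with a `specimen_id` column and one label
#' column per requested scheme (named after the scheme). Optional columns:
#' `exemplar_<scheme>` (TRUE/1 marks that specimen as its species'
#' exemplar) and `discovery_status`. Specimens with an empty label in a
#' scheme are excluded from that scheme (a count is messaged).
#'
#' @param path path to the TSV file.
#' @param scheme_names character vector of scheme (column) names to load.
#' @return named list of `TaxonomyMap`, one per scheme.
#' @export
read_metadata <- function(path, scheme_names) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  if (!"specimen_id" %in% names(tab)) stop("metadata needs a specimen_id column")
  if (anyDuplicated(tab$specimen_id))
    stop("duplicate specimen_id in metadata: ",
         tab$specimen_id[duplicated(tab$specimen_id)][1L])
  status <- if ("discovery_status" %in% names(tab)) {
    s <- tab$discovery_status
    s[is.na(s) | !nzchar(s)] <- "known_historic"
    ok <- c("known_historic", "new_taxon", "new_form_of_existing")
    if (!all(s %in% ok)) stop("unknown discovery_status value(s): ",
                              paste(setdiff(unique(s), ok), collapse = ", "))
    stats::setNames(s, tab$specimen_id)
  } else character()
  out <- lapply(scheme_names, function(sc) {
    if (!sc %in% names(tab)) stop("metadata lacks a column for scheme '", sc, "'")
    lab <- tab[[sc]]
    keep <- !is.na(lab) & nzchar(lab)
    if (any(!keep))
      message(sum(!keep), " specimen(s) have no '", sc,
              "' label and are excluded from that scheme")
    label_of <- stats::setNames(lab[keep], tab$specimen_id[keep])
    excol <- paste0("exemplar_", sc)
    exemplar_of <- character()
    if (excol %in% names(tab)) {
      flag <- keep & tab[[excol]] %in% c("TRUE", "true", "1", "yes")
      if (any(flag)) {
        sp <- lab[flag]
        if (anyDuplicated(sp))
          stop("scheme '", sc, "': two exemplars designated for species ",
               sp[duplicated(sp)][1L])
        exemplar_of <- stats::setNames(tab$specimen_id[flag], sp)
      }
    }
    taxonomy_map(sc, label_of, exemplar_of,
                 discovery_status_of = status[names(status) %in% tab$specimen_id[keep]])
  })
  names(out) <- scheme_names
  out
}

#' Write specimen metadata as a tab-separated file
#'
#' Emits the layout [read_metadata()] reads back: `specimen_id`, one
#' label column per scheme, `exemplar_<scheme>` flags and
#' `discovery_status`.
#'
#' @param set a `SequenceSet` with taxonomies attached.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(set, path) {
  stopifnot(inherits(set, "SequenceSet"), length(set$taxonomies) > 0L)
  out <- data.frame(specimen_id = set$ids)
  status <- character(0)
  for (tx in set$taxonomies) {
    out[[tx$scheme_name]] <- unname(tx$label_of[set$ids])
    out[[paste0("exemplar_", tx$scheme_name)]] <-
      as.integer(set$ids %in% tx$exemplar_of)
    if (length(tx$discovery_status_of)) status <- tx$discovery_status_of
  }
  if (length(status)) {
    st <- unname(status[set$ids])
    st[is.na(st)] <- "known_historic"
    out$discovery_status <- st
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge sequences and taxonomies into a validated dataset
#'
#' Checks that every specimen referenced by any scheme exists in the
#' sequence set, and derives lumping maps between schemes: for each pair of
#' schemes, a label of scheme A that spans >= 2 labels of scheme B gets a
#' `complex_map` entry in scheme A.
#'
#' @param set a `SequenceSet`.
#' @param taxonomies named list of `TaxonomyMap`.
#' @return the `SequenceSet` with taxonomies attached.
#' @export
merge_dataset <- function(set, taxonomies) {
  stopifnot(inherits(set, "SequenceSet"))
  for (tx in taxonomies) {
    missing <- setdiff(names(tx$label_of), set$ids)
    if (length(missing))
      stop("scheme '", tx$scheme_name, "' references specimen(s) absent from ",
           "the sequence set: ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  if (length(taxonomies) >= 2L) {
    for (a in seq_along(taxonomies)) for (b in seq_along(taxonomies)) {
      if (a == b) next
      ta <- taxonomies[[a]]; tb <- taxonomies[[b]]
      shared <- intersect(names(ta$label_of), names(tb$label_of))
      if (!length(shared)) next
      spans <- split(tb$label_of[shared], ta$label_of[shared])
      spans <- lapply(spans, function(v) sort(unique(unname(v))))
      lumped <- spans[lengths(spans) >= 2L]
      if (length(lumped)) taxonomies[[a]]$complex_map <-
          utils::modifyList(as.list(taxonomies[[a]]$complex_map), lumped)
    }
  }
  set$taxonomies <- taxonomies
  set
}

# ---- reading-frame QC -------------------------------------------------------

#' Check a coding sequence for internal stop codons
#'
#' Gaps are removed before translation. With `frame = "auto"` all three
#' frames are translated and the frame with the fewest internal stops is
#' chosen (ties to the lowest frame). Codons containing ambiguity codes
#' translate to X and never count as stops.
#'
#' @param sequence a nucleotide string, character vector of bases, or a
#'   single record taken from a `SequenceSet`.
#' @param code genetic code number passed to [ape::trans()]; default 2
#'   (vertebrate mitochondrial).
#' @param frame 1, 2, 3 or "auto".
#' @return list with `frame`, `has_internal_stop` and `n_internal_stops`.
#' @export
validate_coding <- function(sequence, code = 2, frame = "auto") {
  if (length(sequence) == 1L && is.character(sequence))
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  s <- tolower(as.character(sequence))
  s <- s[s != "-" & s != "?"]
  if (length(s) < 3L) stop("sequence shorter than one codon after gap removal")
  count_stops <- function(f) {
    n_cod <- (length(s) - f + 1L) %/% 3L
    if (n_cod < 1L) return(c(NA_integer_, NA_integer_))
    aa <- as.character(suppressWarnings(
      ape::trans(ape::as.DNAbin(matrix(s, nrow = 1L)),
                 code = code, codonstart = f)))
    internal <- aa[seq_len(max(0L, length(aa) - 1L))]
    c(sum(internal == "*"), sum(aa == "*"))
  }
  frames <- if (identical(frame, "auto")) 1:3 else as.integer(frame)
  stops <- vapply(frames, count_stops, integer(2L))
  ok <- !is.na(stops[1L, ])
  if (!any(ok)) stop("sequence too short to translate in any requested frame")
  pick <- frames[ok][which.min(stops[1L, ok])]
  n_int <- stops[1L, frames == pick][1L]
  list(frame = pick, has_internal_stop = n_int > 0L,
       n_internal_stops = as.integer(n_int))
}

#' Screen every record of a set for premature stop codons
#'
#' @param set a `SequenceSet`.
#' @param code genetic code number (default vertebrate mitochondrial).
#' @return data.frame with one row per specimen: `specimen_id`, `frame`,
#'   `has_internal_stop`, `n_internal_stops`.
#' @export
screen_stop_codons <- function(set, code = 2) {
  stopifnot(inherits(set, "SequenceSet"))
  res <- lapply(set$records, validate_coding, code = code)
  data.frame(specimen_id = set$ids,
             frame = vapply(res, `[[`, 1L, "frame"),
             has_internal_stop = vapply(res, `[[`, TRUE, "has_internal_stop"),
             n_internal_stops = vapply(res, `[[`, 1L, "n_internal_stops"),
             row.names = NULL)
}
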