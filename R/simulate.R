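# Synthetic radiation simulator. Sequences evolve along a species tree
# under a continuous-time 2-parameter (K80-type) substitution process --
# the same model family the K2P estimator assumes -- then each specimen's
# lineage evolves independently for intra_depth/2 below its population's
# ancestral sequence (a star genealogy; only the distance distributions
# matter downstream). Lumping maps, exemplar designations, discovery
# status and mtDNA capture (hybridisation) give every dataset a known
# truth for end-to-end testing.

#' Simulation configuration
#'
#' @param species data.frame with one row per simulated population:
#'   `pop` (tree tip name), `label` (truth species label; a new form
#'   carries its parent species' label), `n` (specimens, >= 1),
#'   `intra_depth` (expected intraspecific pairwise divergence,
#'   subs/site), `status` (`known_historic`, `new_taxon`,
#'   `new_form_of_existing`).
#' @param tree `phylo` or newick string over the `pop` names with branch
#'   lengths in expected substitutions/site; `NULL` gives a star tree
#'   with every population at `star_depth` from the root.
#' @param seed integer seed; a config is reproducible bit for bit.
#' @param seq_length alignment length (default 650, a COI barcode).
#' @param kappa transition/transversion rate ratio (default 4, a typical
#'   mtDNA value).
#' @param lumping named list: historic label -> truth labels it lumps.
#'   Truth labels not covered keep their own name in the historic scheme.
#' @param hybrids list of `list(donor =, recipient =, k =)` truth labels
#'   for mtDNA capture applied after simulation.
#' @param exemplar_rule "first_specimen" or "random".
#' @param codon_screen if TRUE, specimen sequences are re-drawn until
#'   frame-1 translation has no internal stop codon (vertebrate mito).
#' @param star_depth root-to-tip depth of the default star tree.
#' @return list of class `SimulationConfig`.
#' @export
sim_config <- function(species, tree = NULL, seed = 1, seq_length = 650,
                       kappa = 4, lumping = list(), hybrids = list(),
                       exemplar_rule = c("first_specimen", "random"),
                       codon_screen = FALSE, star_depth = 0.05) {
  exemplar_rule <- match.arg(exemplar_rule)
  stopifnot(is.data.frame(species),
            all(c("pop", "label", "n", "intra_depth") %in% names(species)))
  if (!"status" %in% names(species)) species$status <- "known_historic"
  if (anyDuplicated(species$pop)) stop("population names must be unique")
  stopifnot(all(species$n >= 1), all(species$intra_depth >= 0))
  if (length(lumping)) {
    flat <- unlist(lumping)
    if (anyDuplicated(flat)) stop("lumping sets must be disjoint")
    bad <- setdiff(flat, species$label)
    if (length(bad)) stop("lumping references unknown label(s): ",
                          paste(bad, collapse = ", "))
  }
  for (h in hybrids) {
    if (!all(c(h$donor, h$recipient) %in% species$label))
      stop("hybrid spec references unknown label(s)")
    if (h$donor == h$recipient) stop("hybrid donor must differ from recipient")
  }
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!is.null(tree)) {
    if (!setequal(tree$tip.label, species$pop))
      stop("tree tips must match the population names")
  }
  structure(list(species = species, tree = tree, seed = seed,
                 seq_length = as.integer(seq_length), kappa = kappa,
                 lumping = lumping, hybrids = hybrids,
                 exemplar_rule = exemplar_rule, codon_screen = codon_screen,
                 star_depth = star_depth),
            class = "SimulationConfig")
}

# K80 per-site substitution probabilities after distance d (subs/site)
.k80_probs <- function(d, kappa) {
  e1 <- exp(-4 * d / (kappa + 2))
  e2 <- exp(-2 * d * (kappa + 1) / (kappa + 2))
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1            # each of the two transversion targets
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

# evolve an integer-coded sequence (1=a 2=c 3=g 4=t) for distance d
.evolve <- function(seq, d, kappa) {
  if (d <= 0) return(seq)
  p <- .k80_probs(d, kappa)
  u <- stats::runif(length(seq))
  out <- seq
  ts_idx <- u >= p["same"] & u < p["same"] + p["ts"]
  tv1_idx <- u >= p["same"] + p["ts"] & u < p["same"] + p["ts"] + p["tv"]
  tv2_idx <- u >= p["same"] + p["ts"] + p["tv"]
  out[ts_idx] <- ((seq[ts_idx] + 1L) %% 4L) + 1L          # a<->g, c<->t
  pur <- seq %% 2L == 1L
  out[tv1_idx] <- ifelse(pur[tv1_idx], 2L, 1L)
  out[tv2_idx] <- ifelse(pur[tv2_idx], 4L, 3L)
  out
}

.int2char <- function(seq) c("a", "c", "g", "t")[seq]

# frame-1 internal stop codon positions (vertebrate mito: taa/tag/aga/agg)
.stop_codon_starts <- function(seq_int) {
  n_cod <- length(seq_int) %/% 3L
  if (n_cod < 2L) return(integer())
  starts <- 3L * (seq_len(n_cod - 1L) - 1L) + 1L      # internal codons only
  b1 <- seq_int[starts]; b2 <- seq_int[starts + 1L]; b3 <- seq_int[starts + 2L]
  is_stop <- (b1 == 4L & b2 == 1L & (b3 == 1L | b3 == 3L)) |   # taa, tag
             (b1 == 1L & b2 == 3L & (b3 == 1L | b3 == 3L))     # aga, agg
  starts[is_stop]
}

.has_internal_stop <- function(seq_int) length(.stop_codon_starts(seq_int)) > 0L

# draw a descendant; the codon screen re-draws just the sites of any
# codon that mutated into a stop, until the frame-1 translation is clean
.draw_descendant <- function(anc, d, kappa, codon_screen) {
  s <- .evolve(anc, d, kappa)
  if (codon_screen) {
    for (i in seq_len(100L)) {
      bad <- .stop_codon_starts(s)
      if (!length(bad)) break
      idx <- as.vector(outer(0:2, bad, "+"))
      s[idx] <- .evolve(anc[idx], d, kappa)
    }
  }
  s
}

# a random root sequence; under the screen, stop codons are resampled
.draw_root <- function(L, codon_screen) {
  s <- sample.int(4L, L, replace = TRUE)
  if (codon_screen) {
    for (i in seq_len(100L)) {
      bad <- .stop_codon_starts(s)
      if (!length(bad)) break
      idx <- as.vector(outer(0:2, bad, "+"))
      s[idx] <- sample.int(4L, length(idx), replace = TRUE)
    }
  }
  s
}

#' Simulate a barcode dataset with known truth
#'
#' @param cfg a [sim_config()].
#' @return list with `set` (a `SequenceSet` with "current" and "historic"
#'   taxonomies attached), `truth` (the current-taxonomy `TaxonomyMap`)
#'   and `historic` (the lumped scheme). Generator internals needed by
#'   [inject_hybrids()] ride along as `set$sim`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  sp <- cfg$species
  root <- .draw_root(cfg$seq_length, cfg$codon_screen)
  # ancestral sequence per population: evolve down the species tree
  anc <- list()
  if (is.null(cfg$tree)) {
    for (p in sp$pop)
      anc[[p]] <- .draw_descendant(root, cfg$star_depth, cfg$kappa,
                                   cfg$codon_screen)
  } else {
    tr <- ape::reorder.phylo(cfg$tree, "cladewise")
    n_tip <- length(tr$tip.label)
    node_seq <- vector("list", n_tip + tr$Nnode)
    node_seq[[n_tip + 1L]] <- root
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]; chd <- tr$edge[e, 2L]
      node_seq[[chd]] <- .draw_descendant(node_seq[[par]], tr$edge.length[e],
                                          cfg$kappa, cfg$codon_screen)
    }
    for (i in seq_len(n_tip)) anc[[tr$tip.label[i]]] <- node_seq[[i]]
  }
  # specimens: independent lineages of depth intra_depth/2 below the
  # population ancestor
  seqs <- list(); label_of <- character(); status_of <- character()
  pop_of <- character()
  for (r in seq_len(nrow(sp))) {
    p <- sp$pop[r]
    for (i in seq_len(sp$n[r])) {
      id <- sprintf("%s_%02d", p, i)
      seqs[[id]] <- .int2char(.draw_descendant(anc[[p]], sp$intra_depth[r] / 2,
                                               cfg$kappa, cfg$codon_screen))
      label_of[id] <- sp$label[r]
      status_of[id] <- sp$status[r]
      pop_of[id] <- p
    }
  }
  set <- sequence_set(seqs)
  ids <- set$ids
  # exemplars: one known-historic specimen per truth species
  pick_exemplar <- function(cands) {
    if (cfg$exemplar_rule == "first_specimen") cands[1L]
    else cands[sample.int(length(cands), 1L)]
  }
  exemplar_of <- character()
  for (lb in unique(label_of)) {
    cands <- ids[label_of[ids] == lb & status_of[ids] == "known_historic"]
    if (!length(cands)) next                       # wholly new taxa: no exemplar
    exemplar_of[lb] <- pick_exemplar(cands)
  }
  truth <- taxonomy_map("current", label_of, exemplar_of,
                        discovery_status_of = status_of)
  # historic scheme: apply the lumping map to the truth labels
  hist_name <- stats::setNames(unique(label_of), unique(label_of))
  for (h in names(cfg$lumping)) hist_name[cfg$lumping[[h]]] <- h
  hist_label_of <- stats::setNames(unname(hist_name[label_of]), names(label_of))
  hist_ex <- character()
  for (lb in unique(hist_label_of)) {
    cands <- ids[hist_label_of[ids] == lb & status_of[ids] == "known_historic"]
    if (!length(cands)) next
    hist_ex[lb] <- pick_exemplar(cands)
  }
  cmap <- cfg$lumping[lengths(cfg$lumping) >= 2L]
  historic <- taxonomy_map("historic", hist_label_of, hist_ex,
                           discovery_status_of = status_of,
                           complex_map = cmap)
  set <- merge_dataset(set, list(current = truth, historic = historic))
  set$sim <- list(pop_ancestors = anc, species = sp, kappa = cfg$kappa,
                  codon_screen = cfg$codon_screen, pop_of = pop_of)
  for (h in cfg$hybrids)
    set <- inject_hybrids(set, set$taxonomies$current, h$donor, h$recipient,
                          h$k, seed = cfg$seed + 1L)
  list(set = set, truth = set$taxonomies$current,
       historic = set$taxonomies$historic)
}

#' Inject mitochondrial capture (hybridisation) into a simulated set
#'
#' Replaces `k` recipient specimens' sequences with fresh draws from the
#' donor species' intraspecific process; labels are unchanged, so the
#' recipients carry the donor's mtDNA. The recipient's exemplar is never
#' captured when enough other specimens exist.
#'
#' @param set a simulated `SequenceSet` (must carry `$sim` internals).
#' @param truth_tax truth `TaxonomyMap` of the set.
#' @param donor,recipient truth species labels.
#' @param k number of recipient specimens to capture (`k = 0` is a
#'   no-op).
#' @param seed integer seed for choosing the captured specimens.
#' @return the modified `SequenceSet`.
#' @export
inject_hybrids <- function(set, truth_tax, donor, recipient, k, seed = 1) {
  stopifnot(inherits(set, "SequenceSet"))
  if (is.null(set$sim)) stop("set carries no simulator internals")
  if (k == 0) return(set)
  sp <- set$sim$species
  don_pops <- sp$pop[sp$label == donor]
  if (!length(don_pops)) stop("unknown donor label: ", donor)
  rec_ids <- names(truth_tax$label_of)[truth_tax$label_of == recipient]
  if (!length(rec_ids)) stop("unknown recipient label: ", recipient)
  if (k > length(rec_ids))
    stop("k = ", k, " exceeds the ", length(rec_ids),
         " specimens of ", recipient)
  ex <- truth_tax$exemplar_of[recipient]
  cands <- setdiff(rec_ids, ex)
  if (length(cands) < k) cands <- rec_ids
  set.seed(seed)
  captured <- sort(sample(cands, k))
  don_pop <- don_pops[1L]
  anc <- set$sim$pop_ancestors[[don_pop]]
  depth <- sp$intra_depth[sp$pop == don_pop][1L] / 2
  for (id in captured)
    set$records[[id]] <- .int2char(
      .draw_descendant(anc, depth, set$sim$kappa, set$sim$codon_screen))
  set$sim$captured <- c(set$sim$captured, captured)
  set
}

# ---- presets ----------------------------------------------------------------

.preset_gapped <- function(seed) {
  sp <- data.frame(pop = sprintf("sp%02d", 1:20),
                   label = sprintf("sp%02d", 1:20),
                   n = 5L, intra_depth = 0.02)
  sim_config(sp, seed = seed, star_depth = 0.05, codon_screen = TRUE)   # pairwise inter = 10%
}

# A recent radiation scored under a historic taxonomy. Five recently
# diverged species pairs sit at the tips of deep lineages; the historic
# scheme lumps the five "a" populations under one name and the five "b"
# populations under another (one 1977 name spanning several distant
# clusters, as in the maccanni-type complexes), so each population's
# nearest neighbour carries a different historic label while its
# conspecifics (historically speaking) sit a deep divergence away. Three
# further lumped complexes, one mtDNA-capturing hybrid pair and three
# small species round out the fauna. No barcoding gap survives this
# taxonomy.
.preset_skink1977 <- function(seed) {
  pair_pops <- as.vector(t(outer(paste0("P", 1:5), c("a", "b"), paste0)))
  cplx_pops <- c("C1x", "C1y", "C1z", "C2x", "C2y", "C3x", "C3y")
  other <- c("don", "rec", "S1", "S2", "S3")
  sp <- data.frame(
    pop = c(pair_pops, cplx_pops, other),
    label = c(pair_pops, cplx_pops, other),
    n = c(rep(5L, 10), rep(4L, 7), 6L, 6L, 1L, 2L, 3L),
    intra_depth = c(rep(0.005, 10), rep(0.005, 7), 0.005, 0.005,
                    0.004, 0.004, 0.004))
  nwk <- paste0(
    paste(sprintf("(P%da:0.004,P%db:0.004):0.061", 1:5, 1:5),
          collapse = ","), ",",
    "((C1x:0.02,C1y:0.02):0.001,C1z:0.021):0.044,",
    "(C2x:0.02,C2y:0.02):0.045,(C3x:0.02,C3y:0.02):0.045,",
    "(don:0.02,rec:0.02):0.045,S1:0.065,S2:0.065,S3:0.065")
  nwk <- paste0("(", nwk, ");")
  lump <- list(H_A = paste0("P", 1:5, "a"), H_B = paste0("P", 1:5, "b"),
               H_C1 = c("C1x", "C1y", "C1z"), H_C2 = c("C2x", "C2y"),
               H_C3 = c("C3x", "C3y"))
  sim_config(sp, tree = nwk, seed = seed, lumping = lump,
             hybrids = list(list(donor = "don", recipient = "rec", k = 2L)), codon_screen = TRUE)
}

# The same radiation under a revised taxonomy: complexes split, two
# recently diverged pairs retained, hybridising pair retained, no
# singleton species (every species keeps >= 2 sampled specimens).
.preset_skink_current <- function(seed) {
  iso <- sprintf("I%02d", 1:14)
  sp <- data.frame(
    pop = c(iso, "Q1a", "Q1b", "Q2a", "Q2b", "don", "rec"),
    label = c(iso, "Q1a", "Q1b", "Q2a", "Q2b", "don", "rec"),
    n = c(rep(c(2L, 3L, 5L, 8L, 12L, 4L, 6L), 2)[1:14],
          6L, 6L, 6L, 6L, 6L, 6L),
    intra_depth = c(rep(c(0.004, 0.008, 0.006), 5)[1:14],
                    rep(0.005, 6)))
  nwk <- paste0("(", paste(sprintf("%s:0.065", iso), collapse = ","), ",",
                "(Q1a:0.006,Q1b:0.006):0.059,",
                "(Q2a:0.006,Q2b:0.006):0.059,",
                "(don:0.02,rec:0.02):0.045);")
  sim_config(sp, tree = nwk, seed = seed,
             hybrids = list(list(donor = "don", recipient = "rec", k = 2L)), codon_screen = TRUE)
}

# Known reference fauna plus post-revision discoveries: three wholly new
# taxa (one of them historically hidden inside a named complex) and two
# morphologically flagged forms that the truth assigns to existing
# species.
.preset_discovery <- function(seed) {
  base <- sprintf("B%02d", 1:8)
  sp <- data.frame(
    pop = c(base, "N1", "N2", "N3", "B01form", "B02form"),
    label = c(base, "N1", "N2", "N3", "B01", "B02"),
    n = c(rep(5L, 8), 3L, 2L, 3L, 2L, 2L),
    intra_depth = c(rep(0.005, 8), rep(0.004, 3), 0.004, 0.004),
    status = c(rep("known_historic", 8), rep("new_taxon", 3),
               rep("new_form_of_existing", 2)))
  # N1 sits inside what was historically a complex with B03; N2 and N3
  # are isolated deep lineages.
  nwk <- paste0(
    "((B01:0.0025,B01form:0.0025):0.0475,",
    "(B02:0.0025,B02form:0.0025):0.0475,",
    "(B03:0.015,N1:0.015):0.035,",
    paste(sprintf("%s:0.05", base[4:8]), collapse = ","), ",",
    "N2:0.04,N3:0.04);")
  sim_config(sp, tree = nwk, seed = seed,
             lumping = list(H_B03 = c("B03", "N1")), codon_screen = TRUE)
}

#' Named simulation presets
#'
#' `"gapped"`: 20 species x 5 specimens, 2% intraspecific depth, 10%
#' interspecific splits -- a clean global barcoding gap.
#' `"skink1977"`: a recent radiation scored under a coarse historic
#' taxonomy -- cross-labelled close pairs, deep lumped complexes, an
#' mtDNA-capturing hybrid pair; no barcoding gap.
#' `"skink_current"`: the revised-taxonomy analogue -- complexes split,
#' two recent pairs and the hybrid pair retained; a partial gap.
#' `"discovery"`: a known reference fauna plus three new taxa and two new
#' forms for species-discovery scoring.
#'
#' @param name preset name; `NULL` returns all presets as a named list.
#' @param seed seed stored in the returned config(s).
#' @return a `SimulationConfig`, or a named list of them.
#' @export
presets <- function(name = NULL, seed = 1) {
  all <- list(gapped = .preset_gapped,
              skink1977 = .preset_skink1977,
              skink_current = .preset_skink_current,
              discovery = .preset_discovery)
  if (is.null(name)) return(lapply(all, function(f) f(seed)))
  if (!name %in% names(all)) stop("unknown preset: ", name)
  all[[name]](seed)
}
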