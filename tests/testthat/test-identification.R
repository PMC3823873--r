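# Constructed line datasets give exact control over neighbourhoods.

test_that("best match assigns the nearest reference's species", {
  ld <- line_dataset(c(q = 0, a1 = 0.01, a2 = 0.03, b1 = 0.08),
                     c("A", "A", "A", "B"))
  r <- best_match("q", ld$m, ld$tax)
  expect_equal(r$outcome, "success")
  expect_equal(r$assigned, "A")
  expect_equal(r$nearest_id, "a1")
  expect_equal(r$nearest_distance, 0.01)

  # nearest is heterospecific
  ld2 <- line_dataset(c(q = 0, b1 = 0.01, a1 = 0.05), c("A", "B", "A"))
  expect_equal(best_match("q", ld2$m, ld2$tax)$outcome, "misidentified")

  # exact tie across two species
  ld3 <- line_dataset(c(q = 0, a1 = 0.02, b1 = -0.02), c("A", "A", "B"))
  r3 <- best_match("q", ld3$m, ld3$tax)
  expect_equal(r3$outcome, "ambiguous")
  expect_true(is.na(r3$assigned))
})

test_that("best close match adds the no-match outcome", {
  ld <- line_dataset(c(q = 0, a1 = 0.01, b1 = 0.08), c("A", "A", "B"))
  expect_equal(best_close_match("q", ld$m, ld$tax, t = 0.02)$outcome, "success")
  ld2 <- line_dataset(c(q = 0, a1 = 0.05, b1 = 0.08), c("A", "A", "B"))
  expect_equal(best_close_match("q", ld2$m, ld2$tax, t = 0.02)$outcome,
               "no_match")
  # boundary: d == t counts as within
  expect_equal(best_close_match("q", ld2$m, ld2$tax, t = 0.05)$outcome,
               "success")
  # singleton species forced onto a heterospecific nearest within t
  ld3 <- line_dataset(c(q = 0, b1 = 0.01, b2 = 0.02), c("A", "B", "B"))
  expect_equal(best_close_match("q", ld3$m, ld3$tax, t = 0.02)$outcome,
               "misidentified")
})

test_that("all species barcodes inspects the whole neighbourhood", {
  ld <- line_dataset(c(q = 0, a1 = 0.01, a2 = 0.015, b1 = 0.1),
                     c("A", "A", "A", "B"))
  expect_equal(all_species_barcodes("q", ld$m, ld$tax, t = 0.02)$outcome,
               "success")
  ld2 <- line_dataset(c(q = 0, a1 = 0.01, b1 = 0.018), c("A", "A", "B"))
  expect_equal(all_species_barcodes("q", ld2$m, ld2$tax, t = 0.02)$outcome,
               "ambiguous")
  ld3 <- line_dataset(c(q = 0, b1 = 0.01, b2 = 0.015, a1 = 0.2),
                      c("A", "B", "B", "A"))
  expect_equal(all_species_barcodes("q", ld3$m, ld3$tax, t = 0.02)$outcome,
               "misidentified")
  expect_equal(all_species_barcodes("q", ld3$m, ld3$tax, t = 0.005)$outcome,
               "no_match")
})

test_that("distance to exemplar uses exemplar references only", {
  pos <- c(q = 0, a1 = 0.01, aX = 0.02, bX = 0.05)
  ld <- line_dataset(pos, c("A", "A", "A", "B"))
  ld$tax$exemplar_of <- c(A = "aX", B = "bX")
  # nearest exemplar (aX at 0.02) wins although a1 is closer
  r <- distance_to_exemplar("q", ld$m, ld$tax, t = 0.02)
  expect_equal(r$outcome, "success")
  expect_equal(r$nearest_id, "aX")
  # heterospecific exemplar within threshold
  ld2 <- line_dataset(c(q = 0, bX = 0.015, aX = 0.06), c("A", "B", "A"))
  ld2$tax$exemplar_of <- c(A = "aX", B = "bX")
  expect_equal(distance_to_exemplar("q", ld2$m, ld2$tax, t = 0.02)$outcome,
               "misidentified")
  expect_equal(distance_to_exemplar("q", ld2$m, ld2$tax, t = 0.01)$outcome,
               "no_match")
  # an exemplar query is scored against the other exemplars
  r3 <- distance_to_exemplar("aX", ld2$m, ld2$tax, t = 0.1)
  expect_equal(r3$nearest_id, "bX")
  expect_error(distance_to_exemplar("q", ld$m,
                                    taxonomy_map("x", ld$tax$label_of),
                                    t = 0.02), "no exemplars")
})

test_that("matching methods agree with naive classifiers on random data", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(5:12, 1)
    pos <- stats::setNames(runif(n, 0, 0.2), paste0("s", seq_len(n)))
    lab <- stats::setNames(sample(c("A", "B", "C"), n, replace = TRUE),
                           names(pos))
    ld <- line_dataset(pos, unname(lab))
    t <- runif(1, 0.01, 0.1)
    for (q in names(pos)) {
      expect_equal(best_match(q, ld$m, ld$tax)$outcome,
                   naive_best_match(q, ld$m$d, lab))
      expect_equal(best_close_match(q, ld$m, ld$tax, t)$outcome,
                   naive_bcm(q, ld$m$d, lab, t))
      expect_equal(all_species_barcodes(q, ld$m, ld$tax, t)$outcome,
                   naive_asb(q, ld$m$d, lab, t))
    }
  }
})

test_that("threshold relations among the matching methods hold", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    pos <- stats::setNames(runif(n, 0, 0.15), paste0("s", seq_len(n)))
    lab <- sample(c("A", "B", "C"), n, replace = TRUE)
    ld <- line_dataset(pos, lab)
    for (q in names(pos)) {
      bm <- best_match(q, ld$m, ld$tax)
      for (t in c(0.01, 0.04, 0.08)) {
        bcm <- best_close_match(q, ld$m, ld$tax, t)
        asb <- all_species_barcodes(q, ld$m, ld$tax, t)
        # best-close-match equals best-match whenever the nearest is close
        if (bm$nearest_distance <= t) expect_equal(bcm$outcome, bm$outcome)
        # neighbourhood purity implies nearest purity
        if (asb$outcome == "success") expect_equal(bcm$outcome, "success")
      }
      # at t -> infinity best close match reduces to best match
      expect_equal(best_close_match(q, ld$m, ld$tax, t = 1e6)$outcome,
                   bm$outcome)
      # decreasing t never converts no_match into success
      out_by_t <- vapply(c(0.08, 0.04, 0.01), function(t)
        all_species_barcodes(q, ld$m, ld$tax, t)$outcome, "")
      seen_nomatch <- FALSE
      for (o in out_by_t) {
        if (seen_nomatch) expect_equal(o, "no_match")
        if (o == "no_match") seen_nomatch <- TRUE
      }
    }
  }
})

test_that("NJ identification succeeds throughout a clean radiation", {
  sim <- simulate_dataset(presets("gapped", seed = 14))
  tr <- neighbor_joining(build_matrix(sim$set))
  res <- nj_identify(tr, sim$truth)
  expect_equal(nrow(res), 80L)       # 100 specimens minus 20 exemplars
  expect_true(all(res$outcome == "success"))
})

test_that("an unsampled species' clade is flagged as a new candidate", {
  spd <- data.frame(pop = c("A", "B", "New"), label = c("A", "B", "New"),
                    n = c(5L, 5L, 3L), intra_depth = 0.004,
                    status = c("known_historic", "known_historic",
                               "new_taxon"))
  sim <- simulate_dataset(sim_config(spd, seed = 6, star_depth = 0.05))
  tr <- neighbor_joining(build_matrix(sim$set))
  res <- nj_identify(tr, sim$truth,
                     queries = names(sim$truth$label_of)[
                       sim$truth$label_of == "New"])
  expect_true(all(res$outcome == "ambiguous"))
  expect_true(all(res$note == "new_candidate"))
})

test_that("an introgressed query inside the donor clade is misidentified", {
  spd <- data.frame(pop = c("don", "rec", "out"),
                    label = c("don", "rec", "out"),
                    n = c(6L, 6L, 4L), intra_depth = 0.004)
  cfg <- sim_config(spd, seed = 8, star_depth = 0.05,
                    hybrids = list(list(donor = "don", recipient = "rec",
                                        k = 1L)))
  sim <- simulate_dataset(cfg)
  captured <- sim$set$sim$captured
  tr <- neighbor_joining(build_matrix(sim$set))
  res <- nj_identify(tr, sim$truth, queries = captured)
  expect_equal(res$outcome, "misidentified")
  expect_equal(res$assigned, "don")
})

test_that("identify_specimens drives every method over the same queries", {
  sim <- simulate_dataset(presets("gapped", seed = 15))
  m <- build_matrix(sim$set)
  tr <- neighbor_joining(m)
  res <- identify_specimens(m, sim$truth,
                            methods = c("best_match", "best_close_match",
                                        "all_species_barcodes", "exemplar",
                                        "nj"),
                            threshold = 0.05, tree = tr,
                            score_exemplar_queries = FALSE)
  expect_setequal(unique(res$method),
                  c("best_match", "best_close_match", "all_species_barcodes",
                    "exemplar", "nj"))
  # clean gapped data: everything succeeds everywhere
  expect_true(all(res$outcome == "success"))
  expect_error(identify_specimens(m, sim$truth, "nj"), "needs a tree")
  expect_error(identify_specimens(m, sim$truth, "nope"), "unknown method")
})
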