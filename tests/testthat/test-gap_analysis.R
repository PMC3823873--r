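test_that("distance pools follow pair-classification combinatorics", {
  ld <- line_dataset(c(a1 = 0, a2 = 0.01, b1 = 0.1, b2 = 0.12),
                     c("A", "A", "B", "B"))
  pools <- pool_distances(ld$m, ld$tax)
  expect_length(pools$intra_pooled, 2L)
  expect_length(pools$inter_pooled, 4L)
  expect_equal(sort(names(pools$intra_by_species)), c("A", "B"))

  # singleton species: no intra distances, still a nearest neighbour
  ld2 <- line_dataset(c(a1 = 0, a2 = 0.01, s1 = 0.2), c("A", "A", "S"))
  p2 <- pool_distances(ld2$m, ld2$tax)
  expect_false("S" %in% names(p2$intra_by_species))
  expect_equal(unname(p2$nn_dist["S"]), 0.19)
  expect_error(pool_distances(ld2$m, taxonomy_map("x", c(a1 = "A"))),
               "unlabeled")
})

test_that("pools match exhaustive enumeration on a hand-built matrix", {
  pos <- c(x1 = 0, x2 = 0.02, x3 = 0.05, y1 = 0.3, y2 = 0.33)
  lab <- c("X", "X", "X", "Y", "Y")
  ld <- line_dataset(pos, lab)
  pools <- pool_distances(ld$m, ld$tax)
  intra <- c(); inter <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    d <- abs(pos[i] - pos[j])
    if (lab[i] == lab[j]) intra <- c(intra, d) else inter <- c(inter, d)
  }
  expect_equal(sort(pools$intra_pooled), sort(unname(intra)))
  expect_equal(sort(pools$inter_pooled), sort(unname(inter)))
  expect_equal(unname(pools$max_intra["X"]), 0.05)
  expect_equal(unname(pools$nn_dist["X"]), 0.25)
})

test_that("overlap report reproduces hand-enumerated intervals", {
  mk <- function(intra, inter)
    structure(list(intra_pooled = intra, inter_pooled = inter),
              class = "DistancePools")
  # disjoint pools: no overlap
  r0 <- overlap_report(mk(c(0.01, 0.02), c(0.05, 0.06)), 0)
  expect_equal(r0$width, 0)
  expect_equal(r0$pct_observations, 0)
  # worked example: interval [0.03, 0.05], 2 of 6 observations inside
  r1 <- overlap_report(mk(c(0.01, 0.02, 0.05), c(0.03, 0.06, 0.08)), 0)
  expect_equal(r1$lower, 0.03)
  expect_equal(r1$upper, 0.05)
  expect_equal(r1$width, 0.02)
  expect_equal(r1$pct_observations, 100 * 2 / 6)
  expect_error(overlap_report(mk(numeric(), c(0.1)), 0), "non-empty")
})

test_that("overlap equals the enumeration oracle over a small-pool sweep", {
  grid <- seq(0.005, 0.12, length.out = 8)
  set.seed(11)
  for (rep in 1:300) {
    intra <- sample(grid, sample(1:4, 1))
    inter <- sample(grid, sample(1:4, 1))
    for (trim in c(0, 0.05)) {
      pools <- structure(list(intra_pooled = intra, inter_pooled = inter),
                         class = "DistancePools")
      if (trim > 0 && (length(intra) < 2 || length(inter) < 2)) {
        expect_error(overlap_report(pools, trim), "entire pool")
        next
      }
      got <- overlap_report(pools, trim)
      want <- overlap_brute(intra, inter, trim)
      expect_equal(got$lower, want$lower)
      expect_equal(got$upper, want$upper)
      expect_equal(got$width, want$width)
      expect_equal(got$pct_observations, want$pct)
    }
  }
})

test_that("trimming monotonically shrinks the overlap percentage", {
  set.seed(3)
  for (rep in 1:20) {
    pools <- structure(list(intra_pooled = runif(40, 0, 0.08),
                            inter_pooled = runif(60, 0.02, 0.15)),
                       class = "DistancePools")
    pct <- vapply(seq(0, 0.05, by = 0.01),
                  function(tr) overlap_report(pools, tr)$pct_observations, 0)
    expect_true(all(diff(pct) <= 1e-12))
  }
})

test_that("untrimmed overlap bounds are the exact pool extremes", {
  sim <- simulate_dataset(presets("skink1977", seed = 5))
  pools <- pool_distances(build_matrix(sim$set), sim$historic)
  r <- overlap_report(pools, 0)
  expect_identical(r$upper, max(pools$intra_pooled))
  expect_identical(r$lower, min(pools$inter_pooled))
})

test_that("local gap statuses agree with a per-species check", {
  ld <- line_dataset(c(a1 = 0, a2 = 0.01, b1 = 0.05, s1 = 0.2),
                     c("A", "A", "B", "S"))
  tab <- local_gap_table(pool_distances(ld$m, ld$tax))
  expect_equal(tab$status[tab$species == "A"], "gap_present")   # nn .04 > .01
  expect_equal(tab$max_intra[tab$species == "B"], 0)            # singleton
  expect_equal(tab$status[tab$species == "B"], "gap_present")
  # forced tie: nn == max_intra
  ld2 <- line_dataset(c(a1 = 0, a2 = 0.05, b1 = 0.1), c("A", "A", "B"))
  tab2 <- local_gap_table(pool_distances(ld2$m, ld2$tax))
  expect_equal(tab2$status[tab2$species == "A"], "absent_on_line")
  cnt <- attr(tab2, "status_counts")
  expect_equal(unname(cnt["absent_on_line"]), 1L, ignore_attr = TRUE)
})

test_that("a lumped complex loses its local gap under the historic scheme", {
  sim <- simulate_dataset(presets("skink1977", seed = 7))
  m <- build_matrix(sim$set)
  tab_h <- local_gap_table(pool_distances(m, sim$historic))
  # H_A lumps five distant populations: its max intra dwarfs its nn
  expect_equal(tab_h$status[tab_h$species == "H_A"], "absent_below")
  # hybridisation removes the recipient's gap under the truth scheme too
  tab_c <- local_gap_table(pool_distances(m, sim$truth))
  expect_equal(tab_c$status[tab_c$species == "rec"], "absent_below")
})

test_that("the 10x rule is ten times the mean intraspecific distance", {
  mk <- function(intra) structure(list(intra_pooled = intra),
                                  class = "DistancePools")
  expect_equal(threshold_10x(mk(c(0, 0, 0))), 0)
  expect_equal(threshold_10x(mk(c(0.01, 0.03))), 0.2)
  expect_error(threshold_10x(mk(numeric())), "empty")
})

test_that("ABGD splits two tight clusters at a threshold inside the gap", {
  pos <- c(a1 = 0, a2 = 0.004, a3 = 0.009, b1 = 0.2, b2 = 0.205, b3 = 0.211)
  m <- as_dmat(outer(pos, pos, function(x, y) abs(x - y)))
  res <- abgd_partition(m, abgd_config(p_min = 0.002, p_max = 0.05, steps = 8))
  expect_false(res$no_gap)
  expect_equal(res$modal_n_groups, 2L)
  expect_gt(res$consensus_threshold, 0.011)
  expect_lt(res$consensus_threshold, 0.189)
  got <- canon_partition(res$partitions[[
    which(res$per_prior$n_groups == 2L)[1]]])
  expect_equal(got, canon_partition(list(c("a1", "a2", "a3"),
                                         c("b1", "b2", "b3"))))
})

test_that("a uniform distance ladder yields the single-group flag", {
  pos <- stats::setNames(seq(0, by = 0.003, length.out = 14),
                         paste0("t", 1:14))
  m <- as_dmat(outer(pos, pos, function(x, y) abs(x - y)))
  res <- abgd_partition(m, abgd_config(p_min = 0.02, p_max = 0.1, steps = 6))
  expect_true(res$no_gap)
  expect_equal(res$modal_n_groups, 1L)
  expect_length(res$partitions[[1]], 1L)
})

test_that("ABGD recovers the true partition of a gapped simulation", {
  sim <- simulate_dataset(presets("gapped", seed = 12))
  m <- build_matrix(sim$set)
  pools <- pool_distances(m, sim$truth)
  res <- abgd_partition(m)
  expect_equal(res$modal_n_groups, 20L)
  expect_gt(res$consensus_threshold, max(pools$max_intra))
  expect_lt(res$consensus_threshold, min(pools$inter_pooled))
  sel <- which(res$per_prior$n_groups == 20L)[1]
  expect_equal(canon_partition(res$partitions[[sel]]),
               canon_partition(split(m$ids, sim$truth$label_of[m$ids])))
})

test_that("the intraspecific ANOVA matches its closed form", {
  r0 <- anova_intraspecific(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$F, 0)
  r1 <- anova_intraspecific(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r1$F, 1.5)
  expect_equal(r1$df1, 1L)
  expect_equal(r1$df2, 4L)
  set.seed(5)
  for (rep in 1:10) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), mean = 0.3)
    r <- anova_intraspecific(a, b)
    na <- length(a); nb <- length(b)
    gm <- mean(c(a, b))
    ssb <- na * (mean(a) - gm)^2 + nb * (mean(b) - gm)^2
    ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    expect_equal(r$F, (ssb / 1) / (ssw / (na + nb - 2)), tolerance = 1e-10)
    expect_equal(r$df2, na + nb - 2)
    expect_equal(r$p, stats::pf(r$F, 1, na + nb - 2, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  expect_error(anova_intraspecific(1, c(1, 2)), ">= 2")
})

test_that("lumping inflates species-level intraspecific divergence", {
  sim <- simulate_dataset(presets("skink1977", seed = 9))
  m <- build_matrix(sim$set)
  mh <- species_intra_means(pool_distances(m, sim$historic))
  mc <- species_intra_means(pool_distances(m, sim$truth))
  r <- anova_intraspecific(mh, mc)
  expect_gt(mean(mh), mean(mc))
  expect_gt(r$F, 0)
  expect_equal(r$df1, 1L)
})
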