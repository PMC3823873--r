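#!/usr/bin/env Rscript
# Neighbour-joining trees with site-bootstrap support for the two
# taxonomy datasets; newick files feed the tree-based identification.
#
# Run analysis/01_simulate.R first.
# Usage: Rscript analysis/03_trees.R [n_bootstrap] (default 200)

suppressPackageStartupMessages(library(retrobarcode))
n_reps <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(n_reps)) n_reps <- 200L

out <- "results/trees"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (name in c("skink1977", "skink_current")) {
  set <- read_fasta(file.path("results/data", paste0(name, ".fasta")))
  bt <- bootstrap_support(set, n_reps = n_reps, seed = 1)
  write_newick(bt, file.path(out, paste0(name, "_nj.nwk")))
  cat(sprintf("%s: %d tips, %d/%d replicates used, %d%% of internal edges with support >= 70\n",
              name, length(bt$tree$tip.label), bt$n_used, bt$n_reps,
              round(100 * mean(bt$support >= 70))))
}
cat("newick trees written to", out, "\n")
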