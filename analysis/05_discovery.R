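#!/usr/bin/env Rscript
# Species discovery: with references restricted to the species known
# before the revision, can the NJ and exemplar methods tell genuinely
# new taxa from mere new forms of existing species?
#
# Run analysis/01_simulate.R first.
# Usage: Rscript analysis/05_discovery.R

suppressPackageStartupMessages(library(retrobarcode))
out <- "results/discovery"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

set <- read_fasta("results/data/discovery.fasta")
tx <- read_metadata("results/data/discovery.tsv", c("current", "historic"))
set <- merge_dataset(set, tx)
m <- build_matrix(set)
cm <- set$taxonomies$historic$complex_map

as_row <- function(d, method, t) {
  row <- data.frame(method = method, threshold = t,
                    success_pct = d$success_pct)
  for (nm in names(d$counts)) row[[nm]] <- as.integer(d$counts[[nm]])
  row
}

dn <- discovery_assessment(m, set$taxonomies$current, "nj", complex_map = cm)
cat("NJ-based discovery:\n"); print(dn)
rows <- as_row(dn, "nj", NA)

for (t in c(0.02, 0.04, 0.06, 0.08, 0.10)) {
  de <- discovery_assessment(m, set$taxonomies$current, "exemplar", t = t,
                             complex_map = cm)
  cat(sprintf("exemplar t = %2.0f%%: success %3.0f%%\n",
              100 * t, de$success_pct))
  rows <- rbind(rows, as_row(de, "exemplar", t))
}
write.table(rows, file.path(out, "discovery.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("discovery table written to", out, "\n")
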