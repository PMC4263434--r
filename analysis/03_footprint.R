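#!/usr/bin/env Rscript
# Phylogenetic footprinting of the simulated promoter quartet: conserved
# 11-mers at a 0-substitution budget within each lineage pair, and across
# the quartet with one motif loss allowed, on the 1.3-kb upstream windows.

suppressPackageStartupMessages(library(promepi))
dir.create("results", showWarnings = FALSE)

proms <- read_promoters("results/simdata/promoters.fa")
win <- lapply(proms, truncate_upstream, window = 1300)

p34 <- pairwise_conserved(win$PeMADS3p, win$PeMADS4p, k = 11,
                          max_mutations = 0)
p25 <- pairwise_conserved(win$PeMADS2p, win$PeMADS5p, k = 11,
                          max_mutations = 0)
cat(sprintf("pairwise 11-mers, 0 mutations: P3/P4 %d motif(s), P2/P5 %d\n",
            nrow(p34), nrow(p25)))

tree <- ape::read.tree("results/simdata/promoters.nwk")
quartet0 <- substring_parsimony(win, tree, footprint_params(11, 0))
quartet1 <- substring_parsimony(win, tree,
                                footprint_params(11, 0, max_losses = 2))
cat(sprintf("quartet, no losses: %d motif(s); up to 2 losses: %d\n",
            nrow(quartet0), nrow(quartet1)))

flat <- function(m) m[, c("ancestral", "width", "substitutions", "n_lost",
                          "score")]
write.table(flat(quartet1), "results/footprint_motifs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
mm <- motif_map(win, quartet1)
write.table(mm, "results/footprint_map.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("motif map:\n"); print(as.data.frame(mm))
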