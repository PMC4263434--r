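#!/usr/bin/env Rscript
# Generate the synthetic study inputs used by the downstream analysis
# steps: a quartet of promoters evolved along the (P3,P4)/(P2,P5) split
# with planted CArG boxes and planted conserved 11-mers (one lost in one
# lineage), a bisulfite clone set over a heavily methylated region, and
# ChIP-qPCR / dual-luciferase tables with the study's replicate design.

suppressPackageStartupMessages(library(promepi))
outdir <- "results/simdata"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 20140901L

tree <- "((PeMADS3p,PeMADS4p),(PeMADS2p,PeMADS5p));"
prom_spec <- promoter_sim_spec(
  tree, root_length = 1300L, substitution_prob = 0.25,
  planted_carg = list(
    list(decamer = "CCATTAATGG", tss_position = -214L, rule = "core"),
    list(decamer = "CTATATTAAG", tss_position = -750L, rule = "relaxed")),
  planted_motifs = list(
    list(kmer = "ACGTTGCACGA", substitutions = 0L,
         lost = c("PeMADS2p", "PeMADS5p")),
    list(kmer = "GGATCCTTAGC", substitutions = 0L)),
  seed = seed)
sim <- gen_promoters(prom_spec)
write_promoters(sim$promoters, file.path(outdir, "promoters.fa"))
ape::write.tree(sim$tree, file.path(outdir, "promoters.nwk"))
write.table(sim$truth, file.path(outdir, "promoters_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

bs <- gen_bisulfite(epi_sim_spec(ref_length = 400L, seed = seed + 1L))
writeLines(c(">reference", bs$cloneset$reference,
             unlist(lapply(names(bs$cloneset$clones), function(id) {
               c(paste0(">", id), bs$cloneset$clones[[id]])
             }))),
           file.path(outdir, "bisulfite_clones.fa"))
write.table(bs$truth, file.path(outdir, "bisulfite_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

assays <- gen_assays(assay_sim_spec(
  antibody = "H3K9K14ac", region = "ATG",
  tissue_abundance = c(lip = 4.9, petal = 1), ct_sd = 0.15,
  organ_means = c(lip = 3, column = 3, sepal = 1, petal = 1),
  luc_cv = 0.2, n_luc = 6L, seed = seed + 2L))
write.csv(assays$chip, file.path(outdir, "chip_ct.csv"), row.names = FALSE)
write.csv(assays$luciferase, file.path(outdir, "luciferase.csv"),
          row.names = FALSE)
jsonlite::write_json(assays$truth, file.path(outdir, "assay_truth.json"),
                     auto_unbox = TRUE)

cat("simulated inputs written to", outdir, "\n")
cat(sprintf("  promoters: %d leaves x %d bp, %d planted items\n",
            length(sim$promoters), 1300L, nrow(sim$truth)))
cat(sprintf("  bisulfite: %d clones over %d bp\n",
            length(bs$cloneset$clones), nchar(bs$cloneset$reference)))
cat(sprintf("  assays: %d ChIP wells, %d luciferase samples\n",
            nrow(assays$chip), nrow(assays$luciferase)))
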