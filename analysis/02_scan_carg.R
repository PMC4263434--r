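#!/usr/bin/env Rscript
# CArG-box prediction. First reproduces the published per-promoter counts
# from the printed decamer catalog under both consensus rules, then scans
# the simulated promoters and writes hit tables in TSS-relative
# coordinates plus BED6.

suppressPackageStartupMessages({library(promepi); library(dplyr)})
dir.create("results", showWarnings = FALSE)

tab <- pemads_carg_decamers()
counts <- bind_rows(lapply(split(tab, tab$promoter), function(rows) {
  got <- classify_decamers(
    data.frame(label = as.character(rows$location), decamer = rows$decamer),
    list(carg_core(), carg_relaxed()))
  tibble::tibble(promoter = rows$promoter[1], rule = got$rule,
                 n = got$n_matching)
}))
write.table(counts, "results/catalog_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("published catalog, hits per promoter and rule:\n")
print(tidyr::pivot_wider(counts, names_from = rule, values_from = n))

proms <- read_promoters("results/simdata/promoters.fa")
hits <- bind_rows(lapply(proms, function(p) {
  bind_rows(scan_carg(p, carg_core()), scan_carg(p, carg_relaxed()))
}))
write.table(hits, "results/carg_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
hits_to_bed(hits, "results/carg_hits.bed")
cat(sprintf("\nsimulated promoters: %d CArG hits (%d core, %d relaxed)\n",
            nrow(hits), sum(hits$pattern_name == "CCW6GG"),
            sum(hits$pattern_name == "CW8G")))
cat("planted boxes recovered at TSS positions:",
    paste(sort(unique(hits$tss_position[hits$observed %in%
                                          c("CCATTAATGG", "CTATATTAAG")])),
          collapse = ", "), "\n")
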