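#!/usr/bin/env Rscript
# Bisulfite methylation calling on the simulated clone set, per-context
# summary, and methylation-sensitive digestion predictions for the probed
# region (HpaII/MspI single digests and the DraI+HpaII double digest).

suppressPackageStartupMessages(library(promepi))
dir.create("results", showWarnings = FALSE)

fa <- Biostrings::readDNAStringSet("results/simdata/bisulfite_clones.fa")
reference <- as.character(fa[["reference"]])
clones <- as.character(fa[names(fa) != "reference"])
cs <- bisulfite_clone_set(reference, clones, "simulated promoter region")

profile <- call_methylation(cs)
write.table(profile, "results/methylation_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
summ <- methylation_summary(profile)
write.table(summ, "results/methylation_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("per-context methylation:\n"); print(as.data.frame(summ))

# treat sites called at fraction >= 0.5 as methylated for digestion
meth <- profile$position[!is.na(profile$fraction) & profile$fraction >= 0.5]
dig <- digest_predict(reference, meth,
                      enzymes = c("HpaII", "MspI", "DraI", "DraI+HpaII"))
frag <- do.call(rbind, lapply(dig, function(d) {
  data.frame(enzyme = d$enzyme,
             n_sites = length(unlist(d$site_positions)),
             n_blocked = sum(unlist(d$blocked)),
             fragments = paste(d$fragments, collapse = ","))
}))
write.table(frag, "results/digest_fragments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\ndigestion predictions:\n"); print(frag, row.names = FALSE)
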