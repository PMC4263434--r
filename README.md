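# promepi

Toolkit for dissecting the regulatory regions of duplicated B-class MADS-box
genes. Tandem-duplicated paralogs such as *PeMADS2–6* can be near-identical in
coding sequence yet expressed in completely different floral organs; the
explanation lives in their promoters and their chromatin. `promepi`
implements the computational layer of that dissection:

* **CArG-box scanning** — find MADS-protein binding sites under two degenerate
  consensus rules: the core `CC(A/T)₆GG` decamer with a 1-mismatch budget
  ("9 of 10"), and the relaxed `C(A/T)₈G` rule with 0 mismatches. Results are
  reported in TSS-relative coordinates (TSS = +1, no position 0) and export to
  BED6. A curated catalog of 28 published *PeMADS2–6* promoter decamers is
  included (`pemads_carg_decamers()`).
* **Phylogenetic footprinting** — `substring_parsimony()` finds short
  ancestral k-mers conserved across paralogous promoters on a gene tree,
  with a per-leaf substitution budget and an explicit motif-loss model
  (`loss_cost = D + 1`, losses capped by `max_losses`). Exhaustive for
  budgets ≤ 1; exactly-shared runs are merged into maximal blocks.
* **Bisulfite methylation** — conversion-aware clone-to-reference alignment
  (ref-C vs clone-T scored as match), low-identity clone exclusion, per-C
  methylated/unmethylated calls, CpG/CHG/CHH context summaries, and
  methylation-sensitive digestion prediction for HpaII/MspI (CCGG
  isoschizomers with different methyl sensitivity) and DraI, including double
  digests.
* **Assay quantification** — ChIP-qPCR relative enrichment by ΔCt against
  the mark-appropriate control locus (ACTIN2 or Ta3) with delta-method error
  propagation, and dual-luciferase firefly/Renilla ratios with pairwise
  t-tests and compact-letter-display significance groups.
* **Synthetic data** — seeded, byte-deterministic generators for promoter
  quartets evolved along a tree with planted CArG boxes and conserved/lost
  motifs, bisulfite clone sets, and qPCR/luminometer tables — each with a
  ground-truth table, so every algorithm is testable end to end.

See `vignettes/promoter-epigenetics.Rmd` for the methods and parameter
rationale.

## Worked example

Scan a promoter for core-rule CArG boxes, then reproduce the published
decamer classification for one promoter:

```r
library(promepi)

prom <- promoter_record("ex", paste0(
  strrep("GATTACAGGC", 18), "CCATTAATGG", strrep("TTGACCGGAT", 10), "ATG"),
  tss_pos = 291L)
scan_carg(prom, carg_core())
#>   promoter_id start end tss_position strand   observed mismatches pattern_name
#> 1          ex   181 190         -110      + CCATTAATGG          0       CCW6GG

tab <- pemads_carg_decamers()
rows <- tab[tab$promoter == "PeMADS2", ]
classify_decamers(
  data.frame(label = as.character(rows$location), decamer = rows$decamer),
  list(carg_core(), carg_relaxed()))
#>     rule n_matching                  matching_labels
#> 1 CCW6GG          4          -214, -248, -318, -1548
#> 2   CW8G          5 -750, -1254, -1891, -2236, -2586
```

## Analysis workflow

The `analysis/` directory holds numbered driver scripts that run the full
study workflow on simulated inputs, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # promoter quartet, bisulfite clones, assay tables
Rscript analysis/02_scan_carg.R    # catalog counts + CArG hits (TSV + BED)
Rscript analysis/03_footprint.R    # conserved 11-mers, with and without losses
Rscript analysis/04_methylation.R  # methylation calls + digestion predictions
Rscript analysis/05_assays.R       # ChIP enrichment + luciferase letter groups
```

Representative output (seeded, so exactly reproducible):

```
published catalog, hits per promoter and rule:
  promoter CCW6GG  CW8G
1 PeMADS2       4     5
2 PeMADS3       0     2
3 PeMADS4       3     6
4 PeMADS5       3     2
5 PeMADS6       2     1

per-context methylation:
  context n_sites mean_fraction
1     CHG      21     0.4857143
2     CHH      59     0.1118644
3     CpG      28     0.7956989

H3K9K14ac at ATG: lip/petal fold 4.32 +/- 0.30

  group n      mean        sd letters
 column 6 2.9442391 0.6750856       a
    lip 6 2.7939999 0.4530697       a
  sepal 6 1.1096617 0.2378816       b
  petal 6 0.8545915 0.1113566       b
```

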