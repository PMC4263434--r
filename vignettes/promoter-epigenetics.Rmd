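---
title: "Methods: promoter motif scanning, footprinting, and epigenetic assay quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter motif scanning, footprinting, and epigenetic assay quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promepi)
```

`promepi` implements the computational side of a classic promoter-biology
workflow for duplicated MADS-box gene families: predict MADS-protein binding
sites (CArG boxes) in upstream regions, find evolutionarily conserved promoter
elements by phylogenetic footprinting, call cytosine methylation from
bisulfite-sequenced clones, predict methylation-sensitive restriction digests,
and quantify ChIP-qPCR and dual-luciferase reporter assays. A synthetic-data
module generates inputs with known ground truth for every one of these steps.

This vignette records the models, algorithms, and default parameters, and the
rationale for each.

## Coordinates

Promoter positions are reported relative to the transcription start site
(TSS): the TSS base is `+1`, the base immediately 5' of it is `-1`, and there
is no position `0`. Internally sequences are 1-based R strings;
`to_tss_coordinate()` / `from_tss_coordinate()` convert, and `hits_to_bed()`
emits standard 0-based half-open BED6. A `promoter_record()` carries the
sequence together with its local TSS position so all downstream reports agree.

## CArG-box scanning (`scan_carg`)

MADS-domain proteins bind the CArG box. Two degenerate consensus rules are
provided as `consensus_pattern` objects:

* `carg_core()` — `CC(A/T)6GG` (`CCWWWWWWGG`), allowing **1 mismatch**
  anywhere in the decamer ("9 of 10"). This is the classical SRF-type
  consensus with one tolerated deviation.
* `carg_relaxed()` — `C(A/T)8G` (`CWWWWWWWWG`), allowing **0 mismatches**.
  This is the broader plant-database style consensus.

Matching is by per-position membership in the degenerate symbol set
(`W = {A,T}`); an `N` in the sequence counts as a mismatch unless the pattern
symbol itself is `N`. Both decamer patterns equal their own reverse
complements under the degenerate alphabet, so a forward scan already captures
both orientations; `strands = "both"` is supported and deduplicates coincident
intervals. The scanner is vectorized over windows and validated in the test
suite against a naive every-window oracle.

`pemads_carg_decamers()` ships a curated catalog of 28 published decamers
from the PeMADS2–6 promoters with their TSS-relative locations, and
`classify_decamers()` reproduces the per-promoter counts under both rules
(core: 4/0/3/3/2; relaxed: 5/2/6/2/1 for PeMADS2..6). The two rules are
provably disjoint on these decamers: every relaxed-rule row has `W` at
positions 2 and 9, hence at least two mismatches to the core rule.

## Phylogenetic footprinting (`substring_parsimony`)

Conserved elements are modeled as an ancestral k-mer inherited along the gene
tree with a budget of substitutions, optionally lost outright in some leaves.

* **Candidates.** All k-mers observed in any leaf, plus (when
  `max_mutations >= 1`) their 1-substitution neighborhoods. For a budget
  `D <= 1` this candidate set provably contains every optimal ancestral k-mer,
  so the search is exhaustive, not heuristic. `D = 0` takes a fast
  set-membership path.
* **Cost.** For each candidate, the per-leaf cost is the minimum Hamming
  distance to any window of that leaf (a star-decomposition score over the
  validated tree). A leaf may instead be declared *lost* at
  `loss_cost = D + 1` (just above the substitution budget, so loss is never
  preferred over an affordable match), with at most `max_losses` losses
  (default 0) assigned greedily to the costliest leaves only as needed.
* **Merging.** At `D = 0`, runs of overlapping exactly-shared k-mers are
  merged into maximal shared substrings (`merge = TRUE` default), so a 14-bp
  perfectly conserved block is reported once, not as four 11-mers.

Defaults `k = 11`, `max_mutations = 0` reflect the footprinting practice of
demanding near-exact blocks slightly longer than a binding site.
`pairwise_conserved()` is the two-sequence special case and is property-tested
to agree exactly with the tree method on two leaves for `D` in {0, 1}.
`motif_map()` locates each reported motif back in every leaf.

## Bisulfite methylation calling (`call_methylation`)

Sodium bisulfite converts unmethylated C to T (read as T after PCR), while
methylated C is protected. Each sequenced clone is aligned to the untreated
reference by conversion-aware global alignment
(`Biostrings::pairwiseAlignment` with a substitution matrix in which
reference-C vs clone-T scores as a match; gap open 8, extend 4). Clones whose
conversion-aware identity falls below `min_identity = 0.8` are excluded with
a warning (condition class `promepi_bad_clone`) — they are PCR chimeras or
mis-picked clones, not evidence. At each reference cytosine, clone `C` is
called methylated, `T` unmethylated, and anything else (gap, other base) is
excluded per-site. Contexts `CpG`, `CHG`, `CHH` are assigned from the
*reference* sequence (a trailing C is `CHH`), and `methylation_summary()`
aggregates per context.

## Methylation-sensitive digestion (`digest_predict`)

`HpaII` and `MspI` are isoschizomers at `CCGG` (cut after the first C):
`HpaII` is blocked if **either** cytosine of the site is methylated, `MspI`
only by methylation of the **outer** (first) C. The stricter
internal-C-only convention for HpaII is available via
`hpaII_internal_only = TRUE`. `DraI` (`TTTAAA`, cut after position 3) is
methylation-insensitive and serves as the pre-digest in the
`"DraI+HpaII"` combination (cut-set union). Overlapping sites are found with
a lookahead regex, and predicted fragment lengths always sum to the reference
length (property-tested against a cut-and-measure oracle).

## ChIP-qPCR quantification (`relative_enrichment`)

Within each biological replicate, technical-replicate Ct values for the
target amplicon are averaged and normalized against the appropriate control
locus (ΔCt): `ACTIN2` for the active marks H3K4me3 and H3K9K14ac, `Ta3` for
the repressive mark H3K9me2 (`chip_control_region()`). Relative amount is
`efficiency^(-ΔCt)` with `efficiency = 2` (perfect doubling) by default, and
biological replicates are averaged *after* normalization. The reported
standard deviation propagates technical variance by a first-order delta
method: `Var(rel) = (rel · ln eff)^2 (var_t/n_t + var_c/n_c)`.
`fold_between()` compares two estimates of the same antibody/region and
propagates both SDs.

## Dual-luciferase quantification (`luciferase_ratio`, `letter_groups`)

Firefly activity is normalized per-sample by the Renilla co-transfection
control. Organ groups are compared by all pairwise Student t-tests
(`var_equal = TRUE` by default, matching the classical ANOVA-style analysis;
Welch available) at `alpha = 0.01`, and summarized by a compact letter
display built with the insert-and-absorb algorithm: groups sorted by
decreasing mean share a letter iff they are not significantly different. No
multiplicity adjustment is applied by default (`p_adjust = "none"`),
matching common reporting practice for these assays; adjusted options are
available. Type-I behavior of the whole pipeline is calibrated in the test
suite on null data.

## Synthetic data (`gen_promoters`, `gen_bisulfite`, `gen_assays`)

Every generator takes a spec object with an explicit `seed` and is
byte-deterministic.

* **Promoters.** A uniform-random root sequence of `root_length = 1300` bp
  evolves down a user-supplied Newick tree by i.i.d. per-site substitutions
  (Jukes–Cantor-like, `substitution_prob = 0.25` per edge by default — enough
  divergence that chance 11-mer conservation is negligible while planted
  blocks remain recoverable). CArG boxes and conserved motifs are planted
  *after* evolution at declared TSS positions with declared per-leaf
  substitution counts and optional per-leaf loss, with collision checking;
  the returned truth table drives round-trip tests.
* **Bisulfite.** Per-context methylation probabilities default to
  `CpG = 0.8`, `CHG = 0.5`, `CHH = 0.1` (a heavily methylated region with the
  canonical plant context ordering), `conversion_efficiency = 0.99`, sequencing
  `error_rate = 0.001`, `n_clones = 10`.
* **Assays.** Ct values follow `base_ct - log2(abundance) + N(0, ct_sd)` with
  `ct_sd = 0.15` (typical qPCR technical noise), 2 biological × 3 technical
  replicates; luciferase activities are mean-preserving lognormal with
  coefficient of variation `luc_cv = 0.2` and a noisier Renilla channel.

The generators emulate the *statistical structure* of these experiments —
replicate design, noise scale, planted effect sizes — not their biochemistry:
there is no PCR bias model, no strand-specific bisulfite chemistry, no
chromatin context, and promoter evolution ignores indels and selection.
Conclusions about real promoters require real sequences; the synthetic data
exist to give every algorithm a ground truth.

## Limitations

* Footprinting is exhaustive only for substitution budgets `D <= 1`; larger
  budgets would require wider neighborhoods.
* The loss model is all-or-nothing per leaf and costed greedily; it is exact
  for the `loss_cost = D + 1` structure but is not a likelihood model.
* Alignment-based clone calling assumes clones span the whole reference
  region (global alignment with affine gaps).
* Delta-method SDs are first-order and understate uncertainty for very small
  technical replicate counts.
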