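# cendyn

Centromere dynamics from CENH3 ChIP-seq, chromatin marks, non-B DNA and
Hi-C.

## The problem

The functional centromere of a chromosome is the region occupied by the
centromere-specific histone CENH3. When a chromosome is moved into a
foreign genomic background — added as an alien chromosome, introgressed as
a segment, or merged through allopolyploidy — that region can change
size. In cotton, *Gossypium anomalum* centromeres contract in the
*G. hirsutum* background: the chromosome 9 CENH3 domain shrinks from
1.04 Mb (45.67–46.71 Mb) to 0.76 Mb in the addition line and 0.65 Mb in
the introgression line, almost entirely from one arm side. The part of
the parental centromere that loses CENH3 (the variable region, R1)
differs from the part that retains it (the stable region, R2): histone
modification and chromatin accessibility rise more in R1, A-phased DNA
repeats are denser in R2, and new TAD boundaries appear inside the
contracted centromere.

`cendyn` implements that analysis chain as a tested R package for anyone
studying centromere repositioning or contraction with binned functional
genomics data:

* **Domain calling** — per-bin ChIP/Input fold change
  `FC_w = ((chip_w + p)/C) / ((input_w + p)/I)`, domains as maximal runs
  with `FC > 4` (merge gap 100 kb, minimum width 50 kb), parent/derived
  comparison with arm-side loss labels, and the R1/R2 partition
  (R2 = parent ∩ all derived domains, R1 = the remainder; exact in bp).
* **Differential chromatin statistics** — region intensities normalized
  by total read count with two-sided Fisher exact tests; differential
  modification windows (DMWs: fold change > 1.5 and BH-adjusted
  p < 0.05) from a negative-binomial test whose replicate-mean ratio is
  referred to an F distribution, with mode-centred median-ratio
  normalization; pericentromere 1-Mb box profiles over 5-Mb flanks;
  Wilcoxon arm-symmetry tests; Pearson change correlations.
* **Non-B-form DNA** — scanners for seven motif classes (APR, DR, GQ,
  IR, MR, STR, Z-DNA), 200-kb window densities (counts and bp
  coverage), permutation tests of centromeric enrichment (n = 1000),
  and 300-nt/150-nt-step windowed DNA stability scores from unified
  nearest-neighbor duplex free energies.
* **Hi-C structure** — Knight–Ruiz balancing, log2 comparative maps,
  A/B compartments from PC1 of the O/E correlation matrix, TADs from
  insulation-score minima, and boundary comparisons annotated with DMWs.
* **Synthetic data with planted truth** — NB count tracks with planted
  centromeres and contraction, genomes with planted motifs, contact
  matrices with planted compartments and TAD boundaries. Every stage is
  validated by recovering what was planted.

## Worked example

The config-driven pipeline runs every stage on the built-in synthetic
system (a 20-Mb chromosome with a 1-Mb planted centromere losing its
first 0.4 Mb in the derived sample, mark elevation ×3 in R1 and ×1.5 in
R2, a genome with a planted APR block, and contact matrices with two
planted extra boundaries):

```r
library(cendyn)
cfg <- validate_config(list(seed = 42, outdir = tempfile()))
res <- run_pipeline(cfg)

res$comparison
#> domain comparison: delta 0.40 Mb, retained 0.60, loss short-arm
res$partition
#> centromere partition: R1 0.40 Mb (variable), R2 0.60 Mb (stable)
res$region_fc
#>       mark region fold_change       p_value
#> 1 H3K36me2     R1    2.489308  0.000000e+00
#> 2 H3K36me2     R2    1.380322  1.385500e-87
#> 3  H3K27ac     R1    1.902484 1.396591e-272
#> 4  H3K27ac     R2    1.305391  1.741862e-57
res$dmw_counts
#>              mark up down
#> H3K36me2 H3K36me2 40    0
#> H3K27ac   H3K27ac 13    1
res$nonb$permutation$p_value
#> [1] 0.000999001
res$boundary_comparison$gained
#> [1] 41 80
```

Reading the output: the planted 0.4-Mb loss and the R1/R2 partition are
recovered exactly at bin resolution; the R1 region fold changes (2.49 and
1.90) sit below the planted multipliers (3 and 2) because normalization
by total read count absorbs part of the planted elevation — the same
property the real analysis has; all 40 R1 windows are up-regulated DMWs
for the ×3 mark; the planted APR block is significantly centromeric
(smallest attainable permutation p, 1/1001); and the two planted extra
TAD boundaries (bins 40 and 80) are the two gained boundaries.

Individual stages are plain functions (`call_enrichment_domains()`,
`partition_variable_stable()`, `call_dmws()`, `scan_motifs()`,
`permutation_enrichment()`, `window_free_energy()`, `balance_matrix()`,
`compartment_pc1()`, `find_tads()`, …); see the package vignette
(`vignettes/centromere-dynamics.Rmd`) for the models, parameters and
design decisions, and `inst/scripts/cendyn` for a shell entry point.

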