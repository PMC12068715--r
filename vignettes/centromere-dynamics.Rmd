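---
title: "Quantifying centromere contraction and its chromatin correlates"
author: "cendyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying centromere contraction and its chromatin correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cendyn)
library(GenomicRanges)
```

# The scientific problem

When a chromosome moves into a foreign genomic background — as an added
alien chromosome, an introgressed segment, or through allopolyploid
formation — its functional centromere, operationally defined by the
chromatin occupancy of the centromere-specific histone CENH3, can change
size. In cotton, *Gossypium anomalum* (Ga, B genome) centromeres contract
when transferred into *G. hirsutum* (Gh): the chromosome 9 CENH3 domain of
1.04 Mb in Ga shrinks to 0.76 Mb in the addition line (AL9) and 0.65 Mb in
the introgression line (IL9), almost always from one chromosome-arm side.
The part of the parental centromere where CENH3 binding is lost in derived
lines (the variable region, R1) differs epigenetically from the part that
retains binding (the stable region, R2): histone-modification and
chromatin-accessibility elevation is stronger in R1, A-phased DNA repeats
(APRs) are denser in R2, and Hi-C shows new TAD boundaries appearing
inside the contracted centromere.

`cendyn` re-implements this analysis chain as a tested, reusable pipeline:

1. **centromere domains** — CENH3 ChIP/Input fold-change domain calling,
   parent/derived comparison, R1/R2 partition;
2. **differential chromatin statistics** — region Fisher tests,
   differential modification windows (DMWs), pericentromere profiles,
   arm-symmetry tests, accessibility-modification change correlations;
3. **non-B-form DNA** — seven motif-class scanners, windowed densities,
   permutation enrichment, windowed DNA stability scores;
4. **Hi-C structure** — Knight-Ruiz balancing, comparative log2 maps, A/B
   compartments from PC1, insulation-score TADs, boundary comparison;
5. **synthetic data** — generators that plant all of the above as known
   ground truth, which is how the package validates itself.

# Models and procedures

## Domain calling and the R1/R2 partition

Per-bin enrichment is the library-normalized ChIP/Input ratio
$FC_w = \frac{(c_w + p)/C}{(i_w + p)/I}$ with pseudocount $p$ (default 1
read). Domains are maximal runs of bins with $FC > 4$ — the retention rule
used to define functional centromeres from CENH3 peaks — merged across
gaps of at most `merge_gap` (default 100 kb) and filtered to at least
`min_width` (default 50 kb). Those defaults reflect that published
centromere calls are megabase-scale and contiguous; both are exposed.
Raising the threshold can only shrink domains (a tested invariant).

Given a parental domain and one or more derived domains, R2 is the parent
intersected with *all* derived domains and R1 the remainder, so
$R1 \cup R2 = \text{parent}$ and $R1 \cap R2 = \emptyset$ exactly, in base
pairs. Loss directionality is labelled per arm side when at least 80% of
the lost base pairs fall on one side ("almost unidirectional" loss has no
printed numeric rule; 80% is this package's choice, configurable). Printed
megabase coordinates are interpreted as values rounded to 0.01 Mb, so any
comparison against published coordinates carries a ±0.05 Mb tolerance on
derived sizes (the published R1 = 0.37 / R2 = 0.64 Mb are not exactly
reproducible from the published rounded domain coordinates, which give
0.41 / 0.63 Mb).

## Differential statistics

Region intensities are raw counts (windows assigned by midpoint) divided
by the library size; region contrasts use the two-sided Fisher exact test
on the 2×2 table of in-region versus out-of-region reads, exactly the
normalisation printed for region fold changes. The per-window DMW caller
implements two tests behind one interface: a pooled-count exact
(hypergeometric) test, appropriate for Poisson noise, and the default
negative-binomial ratio test — the mean of $R$ NB counts with mean $\mu$
and dispersion $\phi$ is well approximated by a Gamma with shape
$R\mu/(1+\phi\mu)$, so under the null the normalized mean ratio follows
an F distribution with those shapes; using the F rather than a normal
approximation keeps far-tail p-values calibrated, which is exactly where
BH thresholds live. The common dispersion is a ratio-of-means moment
estimator, $\hat\phi = \sum(s^2-\bar m)/\sum(\bar m^2 - s^2/n)$, which
is unbiased where a mean or median of per-window ratios is not at two
replicates. Normalization defaults to median-ratio size factors with the
between-condition scale recentred at the kernel-density mode of the log
fold-change distribution and a final pass restricted to null-looking
windows: a one-sided block of truly changed windows shifts a plain
median (and library totals even more), producing directional false
calls, while the null windows' modal peak stays put for any changed
fraction below half. The assumption that the modal window is unchanged
is stated, not hidden; pure library normalization remains available.
P-values are BH-adjusted per contrast and a DMW requires both fold
change > 1.5 (either direction) and adjusted p < 0.05. The fold change
uses pseudocount 0.5 on mean counts. The engine is deliberately in-repo
rather than a wrapper; validation is by planted truth recovery, and an
independent package implementing the same kind of test serves only as a
cross-check in the test suite.

Pericentromere profiles aggregate normalized intensity in 1-Mb boxes over
5-Mb flanks (clipped boxes are flagged), arm symmetry is an unpaired
two-sided Wilcoxon rank-sum test on per-window changes (the two arms
contain different windows, so a paired test is not meaningful), and
accessibility-modification coupling is a Pearson correlation with its
usual t-test.

## Non-B-form DNA

Seven motif classes are scanned with explicit, config-exposed rules
(defaults in `scan_motifs()`): A-phased repeats (≥3 tracts of 3-9 A's or
T's with 4-9 bp spacers — the minimum spacer is the published rule, the
9-bp maximum keeps tracts in helical phase and is this package's choice),
direct repeats (unit 10-50 bp, ≥2 exact tandem copies), G-quadruplex
(`G{3,}(N{1,7}G{3,}){3,}`, both strands, possessive G-runs), inverted and
mirror repeats (arms ≥10 bp, loop ≤100 bp), short tandem repeats (unit
2-9 bp, span ≥20 bp), and Z-DNA (≥12 bp of alternating purine/pyrimidine
GC/CA steps). Homopolymer runs qualify in no class: a poly-C tract is not
a repeat "motif", and mononucleotide A/T runs enter the analysis as APR
tracts, not as degenerate STRs or mirror repeats. Hits are maximal (no
hit contained in another of its class); scanners are validated against
exhaustive substring-rule oracles on random sequences.

Windowed density (200-kb windows) is reported both as midpoint counts and
merged-bp coverage, since either reading of "density" is defensible.
Centromeric enrichment uses a permutation test (default n = 1000) drawing
centromere-sized window sets from the non-centromeric pool, one-sided,
with the add-one correction, so the smallest attainable p is 1/1001.

DNA stability is scored in 300-nt windows stepped by 150 nt. The default
engine is the unified nearest-neighbor duplex free energy (sum of
dinucleotide stack ΔG°37 terms plus terminal initiation, kcal/mol; more
negative = more stable). This is a deliberate design decision: the
package's comparisons (R1 vs R2 vs non-centromeric windows, Wilcoxon) are
engine-consistent, and an `external` engine hook ingests scores computed
by any dedicated single-strand folding program for users who want MFE
folding energies. Absolute values from the two engines differ; ranks of
AT-rich versus GC-rich windows largely do not.

## Hi-C

Contact matrices are symmetric binned counts (triplet-TSV interchange).
Knight-Ruiz balancing finds the symmetric scaling $DMD$ with equal row
sums via the fixed-point iteration $x \leftarrow x\sqrt{\bar r / r}$,
$r = x \circ (Mx)$, converged when the row-sum coefficient of variation
drops below `tol` (1e-6); zero-marginal bins are masked first, and
non-convergence is an error, never a silent pass-through. The result is
cross-checked against an alternating Sinkhorn oracle in the tests.

Compartments: observed/expected by per-diagonal means, Pearson
correlation matrix, first eigenvector. The A/B sign convention (positive
PC1 = A) is anchored by correlating PC1 with a user-supplied orientation
track (gene density in real data; in the synthetic system, the planted
labels or the parental PC1). PC1 is reported as the unit-norm
eigenvector, so magnitudes are comparable across samples of the same
segment; per-region magnitude ratios are rounded to 2 decimals as
printed.

TADs: per-bin insulation is the mean of contacts in a `window`-bin square
crossing the diagonal, log2-normalized to its chromosome mean. Boundaries
are insulation minima with prominence ≥ `delta` whose cross-boundary O/E
contacts are depleted relative to within-block O/E contacts by a
one-sided rank test (BH across candidates, cutoff `alpha` = 0.01). This
is a single-scale approximation of the multi-scale TAD-separation score
of the referenced tool; accordingly the package's claim is planted
boundary recovery (±2 bins), not reproduction of published TAD counts,
which would require the original sequencing data. Boundary comparison
matches greedily within a slack (default 2 bins) and annotates gained
boundaries with overlapping features such as DMW intervals.

# The synthetic-data generators

The generators define the conditions under which every claim is tested:

* **Count tracks.** Input counts are negative binomial with background 50
  reads per 10-kb bin and dispersion 0.05 (Poisson at 0); NB is the
  standard ChIP-seq count model and what the DMW-style analysis assumes.
  ChIP means are multiplied by the enrichment fold (default 10) inside
  the planted centromere. Libraries are realised totals. Replicates share
  the truth and draw independent noise from derived sub-seeds, giving
  replicate correlations above 0.9 on a structured genome, consistent
  with the >0.93 reported for the real replicates.
* **Contraction systems.** The derived sample loses CENH3 enrichment over
  the planted loss intervals (R1-truth); histone-mark tracks are elevated
  by per-mark R1/R2 multipliers inside the centromere and by a multiplier
  decaying exponentially (scale 1 Mb by default) into the 5-Mb flanks.
  The elevation magnitudes are free parameters of the simulation — the
  study reports fold-change ranges, not physical effect sizes — so the
  test surface is parameter *recovery*, not matching printed folds.
  Exponential decay is the simplest monotone choice for elevation that
  "diminishes with distance" and makes the scale a recoverable parameter.
* **Genomes.** I.i.d. background at a target GC with canonical motif
  instances planted verbatim at recorded positions.
* **Contact matrices.** Power-law distance decay (exponent 1), a
  same-compartment affinity boost, a within-TAD block boost, Poisson
  counts symmetrised from the upper triangle.

What the generators do *not* emulate — sequence-composition bias in ChIP,
mappability, repeat-driven coverage structure, Hi-C ligation artefacts,
trans contacts — bounds what passing tests show: they certify the
*estimators* (callers, tests, balancers) against the stated noise models,
not the upstream read processing, which is out of scope by design (raw
reads are ingested as binned counts).

# Numerical choices and degenerate inputs

* Window grids keep the truncated trailing window; reads map to windows
  by midpoint (no double counting; the source analyses did not state an
  assignment rule).
* Intervals are held as `GRanges` (1-based, closed) — the native
  container of the R genomics stack — and converted to/from 0-based
  half-open BED/bedGraph at I/O boundaries by `rtracklayer`. All width
  arithmetic and partition identities are exact in bp either way.
* Zero-count bins: enrichment uses pseudocount 1; with pseudocount 0,
  both-zero bins report FC 1 and zero-input bins are an error rather than
  an Inf.
* Fully tied rank tests report p = 1 (the normal approximation would be
  0/0).
* Permutation p uses the add-one correction, so it is never 0.
* The PC1 sign without an orientation anchor is fixed deterministically
  (largest-magnitude loading positive) but is only interpretable with an
  anchor.
* Sub-seeds for independent streams are derived as
  `(seed * 7919 + k * 104729) mod (2^31 - 1)`, keeping every seed a
  32-bit integer.

# Problem sizes used in the checks

The validation suite and the acceptance script run, per fixed seed:
50-seed domain recovery on 10-Mb chromosomes (1,000 bins, enrichment
fold 10, background 50 reads/bin, dispersion 0.05, replicates pooled);
20-seed R1/R2 partition recovery from called domains; 40-seed DMW
recovery on 2-Mb segments of 400 5-kb windows with replicate libraries
of 10 million reads, a planted ×3 block covering a fifth of the windows
(comparable to the fraction of windows that change in the real
centromere-focused contrasts — the false-discovery margin of BH testing
is set by the null fraction, so an almost-all-null design would pin the
expected FDR against its own bound), and false discoveries pooled over
seeds; 400-repetition calibration of the permutation and Wilcoxon
nulls; compartment and TAD recovery on 100-200-bin matrices; and
scanner-oracle equivalence on random 250-600-bp sequences per class
(the exhaustive substring oracle is quadratic, so oracle sequences are
short while scanner inputs elsewhere are 50-200 kb). These sizes were
chosen so each recovery statistic is estimated from enough draws to be
stable at the asserted thresholds.

# Known limitations

* The FC-run domain caller replaces a full peak caller; subdomain fine
  structure below `min_width` is intentionally out of scope.
* The NB Wald DMW test is asymptotic; at very low counts (mean below ~5
  per window) the pooled exact test is the better choice.
* Free-energy scores are duplex nearest-neighbor sums, not MFE folds;
  use the external engine for folding-based scores.
* TAD calling is single-scale; boundary counts are parameter-dependent
  and should be compared only within a fixed parameter set.
* The Hi-C module operates on a single segment matrix by construction;
  trans contacts and inter-segment normalisation are not modelled.

# A worked example

```{r example, eval = FALSE}
cfg <- validate_config(list(seed = 42, outdir = tempfile()))
res <- run_pipeline(cfg)
res$comparison          # parent vs derived domain, loss sides
res$partition           # R1/R2 sizes
head(res$region_fc)     # per-mark R1/R2 fold changes + Fisher p
res$boundary_comparison # gained TAD boundaries vs parent
```

The README shows the same run with the numbers it prints.
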