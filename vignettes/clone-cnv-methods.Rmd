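---
title: "Methods: de novo CNV and copy-neutral LOH discovery in cloned genomes"
author: "cloneCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo CNV and copy-neutral LOH discovery in cloned genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneCNV)
```

## The problem

Animals produced by somatic cell nuclear transfer (SCNT) carry the nuclear
genome of a single donor, so any copy-number difference between a clone and
its donor must have arisen mitotically, after cloning. cloneCNV implements
the discovery-and-validation workflow for such *de novo* events: two-channel
array-CGH against the donor as hybridisation reference detects candidate
copy-number variants (CNVs); three orthogonal experiments — dye-swap
array-CGH, SNP-array B-allele profiles, and multi-point genomic qPCR —
validate their existence and boundaries; interval statistics place the calls
in genomic context; and a microsatellite panel establishes that donor and
clone are the same genome in the first place.

Because each clone is hybridised against its own donor, every CNV the array
detects is by construction de novo — there is no population reference to
subtract.

## Signal models

**Array-CGH.** A probe at a locus with clone copy number $c$ and donor
(baseline) copy number $b$ reports $\log_2(c/b)$ plus Gaussian noise. A
single-copy gain on a diploid baseline sits at $\log_2(3/2) \approx 0.585$,
a single-copy loss at $-1$. Copy-neutral events leave the aCGH signal flat.
A homozygous deletion has no finite log ratio; the generator saturates it at
$-3$, as observed ratios do on real arrays.

**Dye swap.** Exchanging the fluorophores of test and reference inverts the
true signal ($\mu \mapsto -\mu$) while the noise is drawn afresh — the swap
is a new hybridisation, not the negation of the forward noise realisation.
A concordant inverted call is strong evidence against dye- or
hybridisation-specific artifacts.

**SNP array.** Each SNP reports total intensity (LRR, centred at
$\log_2(c/2)$) and B allele frequency (BAF, centred at $k/c$ for $k$ copies
of the B allele). In a three-copy region heterozygotes split into bands at
$1/3$ and $2/3$; in copy-neutral LOH the heterozygous band disappears while
LRR stays at 0. BAF noise is Gaussian truncated to $[0,1]$ — a beta or
mixture model would be more faithful in the tails, but the analysis uses
only band locations, so the simpler model suffices.

**qPCR.** Relative copy number is $2^{-\Delta\Delta C_t}$ with the target
normalised against a diploid control locus within each DNA and expressed
relative to the donor calibrator. The generator assumes ideal efficiency 2
(configurable), matching the quantification model the analysis applies; no
efficiency correction is estimated.

## Segmentation

Probe-level log2 ratios are segmented per chromosome. Runs are first broken
wherever adjacent probes lie more than `max_gap` (default 1 Mb) apart —
coverage gaps are array artifacts and are never bridged. Within a run the
package applies recursive rank segmentation:

1. Rank the log2 ratios of the run.
2. Scan contiguous candidate segments over a geometric grid of widths
   (ratio 1.2), comparing each segment's rank sum against the rest of the
   run with the Wilcoxon–Mann–Whitney normal approximation (tie-corrected).
   Candidates must leave each flank either empty or with at least
   `min_probes` probes.
3. Refine the winning candidate's two edges coordinate-wise within a local
   halo, maximising the same $|z|$; the grid quantises widths, and without
   refinement boundaries would land near, not on, change points.
4. Accept the split if its p-value is at most `alpha` (default $10^{-6}$);
   below 50 probes the p-value comes from 999 permutations of the run
   rather than the normal approximation. An accepted candidate splits the
   run three ways; recursion continues in all children.

The segment-vs-rest contrast (rather than a single prefix-vs-suffix
breakpoint statistic) is the essential design choice: a lone breakpoint
statistic dilutes a short embedded event against an entire chromosome and
has essentially no power for, say, a 100-probe event among 16,000 probes,
whereas the windowed contrast concentrates it. Prefix and suffix candidates
are included, so a clean terminal step still reduces to the classical
binary split, exactly at the change point. Ties in the scan are broken
leftmost-first for determinism. The permutation floor ($\approx 10^{-3}$
at 999 permutations) exceeds `alpha`, so runs under 50 probes are in effect
never split — a deliberate conservatism: events that matter are isolated by
splitting large runs at their boundaries.

Significance is per boundary test; no genome-wide multiplicity correction
is layered on top. At $\alpha = 10^{-6}$ and $\sim 10^4$ correlated candidate
tests per chromosome the expected false-split rate per genome stays below a
few percent, which the event-free specificity suite measures directly.

Segments with mean log2 ratio above `gain_thr` (+0.2) or below `loss_thr`
(−0.2) and at least `min_probes` (5) probes become calls. Adjacent
same-direction calls separated only by a coverage-gap break are merged;
same-direction neighbours separated by a significant boundary are kept
apart, since they represent distinct copy levels.

## Validation stages

**Dye-swap concordance.** A forward call passes if a swap call of the
opposite direction overlaps it with reciprocal overlap at least
`min_reciprocal` (default 0.5; the source analyses judged concordance
visually, so the threshold is an explicit package choice). An empty swap
call set fails all forward calls — the experiment ran and showed nothing.

**BAF / LOH.** Samples must pass LRR quality control (autosomal LRR SD
below 0.24). Heterozygous SNPs (BAF in (0.2, 0.8)) are segmented on the
mirrored statistic $|BAF - 0.5|$ with the same segmentation engine — one
engine, two tracks. A segment at least `min_window` (360 kb) wide whose het
BAFs form two clusters at $0.5 \pm d$ with $d \ge$ `mode_delta` (0.08) is
imbalanced; fewer than 10 het SNPs is indeterminate. The defaults separate
the three-copy mode shift ($d = 1/6 \approx 0.167$) from BAF noise (0.03)
with wide margin; none of these numbers is printed in the source analyses,
and all are configurable. The 360 kb window is a conservative default taken
from a denser platform's recommended LOH window. Copy-neutral LOH is called
on maximal het-free runs spanning at least `min_window` whose zero-het
probability $(1 - \hat{h})^{n}$ (genome-wide het rate $\hat{h}$) falls
below $10^{-6}$ and whose mean LRR stays within `lrr_neutral` (0.1) of zero
— the copy-neutrality gate that keeps deletions, which also erase
heterozygotes, out of the LOH table.

**qPCR verdicts.** Fold changes at least 1.4 classify as gain and at most
0.7 as loss — midway between neutral (1.0) and the single-copy expectations
(1.5, 0.5); the thresholds are package defaults, not published values. A
call is `validated` when all inside points classify concordant and all
outside points neutral, `not_validated` when no inside point is concordant,
`indeterminate` otherwise; the refined boundary brackets each breakpoint
between the outermost concordant inside point and the innermost neutral
outside point.

## Interval statistics

Overlap between a call set and a database counts a query interval once if
it shares at least 1 bp (half-open coordinates; abutting intervals do not
overlap). Enrichment is tested by reshuffling each interval uniformly
within its own chromosome, preserving lengths and per-chromosome counts;
permuted intervals may overlap each other and their original positions,
which keeps the null exactly uniform. The p-value is the fraction of
permutations whose overlap count strictly exceeds the observed one,
reported as "< 1/n_iter" when none does. Because ties count as
not-greater, the p-value is conservatively biased when the null overlap
count is nearly degenerate; the calibration suite therefore uses fixtures
whose null count has spread (SD ≈ 4).

Repeat-class context is profiled as the covered fraction of each region —
the CNV union and disjoint flanking annuli at 10 kb, 100 kb, 1 Mb and
10 Mb offsets (both vicinity scales discussed in the source analyses are
provided), clipped at chromosome ends and excluding the CNV union.

## Probability of identity

For allele frequencies $p_i$, the probability that two individuals share a
genotype is, under Hardy–Weinberg equilibrium,
$PI = 2\left(\sum_i p_i^2\right)^2 - \sum_i p_i^4$, and for full siblings
$PI_{sibs} = \tfrac14 + \tfrac12\sum_i p_i^2 +
\tfrac12\left(\sum_i p_i^2\right)^2 - \tfrac14\sum_i p_i^4$. Multilocus
values multiply per-locus PIs under locus independence. Both closed forms
are verified in the test suite against an independent brute-force
enumeration of genotype space (and, for siblings, of parental genotype
pairs), to $10^{-12}$. Allele frequencies must be supplied (or simulated);
published PI values for specific breed panels depend on unpublished
frequency tables and are not reproduced.

## What the generators emulate — and what they do not

The synthetic cohort reproduces the statistical structure the analysis
relies on: segment means at dosage log-ratios, independent Gaussian probe
noise, dye-swap sign inversion with fresh noise, BAF bands at allele-dosage
ratios, het-free LRR-neutral LOH runs, ideal-efficiency qPCR triplicates,
and HWE microsatellite genotypes. It does not emulate GC waves, spatial
artifacts, probe-specific response, BAF asymmetry near 0 and 1, genotyping
error, or mosaicism (partial-cell-fraction events) — so passing tests show
the pipeline's statistical behaviour under its stated model, not robustness
to platform-specific artifacts. Default operating conditions: 3.3 kb probe
spacing and 13 kb SNP spacing (the platforms' densities), aCGH noise SD
0.15, BAF noise 0.03, LRR noise 0.15 and heterozygosity 0.30 — the noise
levels are package choices (no platform noise parameters are published),
set so that clean samples pass the LRR QC threshold with margin while the
segmentation task remains non-trivial (single-copy signal ≈ 4 noise SDs).

## Numerical and design notes

- Coordinates are 0-based half-open internally; report tables print a
  1-based start with end = start + length, so printed end − start equals
  the length in bp. The bundled de novo CNV catalog follows the same
  arithmetic (its chromosome X and 19 rows are exactly consistent with it;
  the three small-CNV rows differ by one bp in the original source, an
  internal inconsistency this package resolves in favour of end − start).
- One global seed fans out to per-stage child seeds by fixed offsets, so
  any stage can be re-run alone and reproduce its output; fixed
  config + seed gives byte-identical reports.
- Sex-chromosome baseline ploidy is configurable per chromosome (a male
  donor's X is hemizygous when the reference is female); default baseline
  is 2 everywhere.
- Simulated genomes in the test and acceptance suites use single
  chromosomes of 20–110 Mb (6,000–33,000 probes) and event sizes of
  24–1,575 probes; recovery and specificity are measured over 50–100
  seeded replicates, and permutation calibration over 200 datasets of 200
  iterations. These sizes keep the suites exact replicas of the workflow
  at reduced genome scale.
- Overlapping truth events of conflicting kind are rejected by the
  generators: inside such a region the expected LRR/BAF signal would be
  ambiguous. Consequently the demonstration cohort places clone-6's 36 kb
  loss outside its 37 Mb LOH region.

## Known limitations

- The segmentation p-value is asymptotic for runs of 50+ probes; for
  heavy-tailed noise the permutation fallback would be more robust but is
  limited to short runs for speed.
- `detect_allelic_imbalance` reports band centres by cluster means, which
  is biased toward 0.5 when the noise is large relative to the mode
  separation; at the default settings the bias is well under the reporting
  tolerance.
- LOH boundaries are resolved to the first/last homozygous SNP of the run;
  the true boundary lies up to a geometric run-in (~1/het-rate SNP
  spacings) outside.
- The qPCR verdict treats assay points as exchangeable; it does not model
  position-dependent amplification quality.
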