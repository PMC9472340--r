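---
title: "Models and methods behind homeoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind homeoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeoscan)
```

homeoscan analyses nascent allopolyploids — hybrids carrying two complete
parental subgenomes, here called R and C — at the level of homoeolog pairs:
one R-subgenome gene matched to its C-subgenome counterpart (or, in the
parents, the orthologous gene pair). This vignette explains the statistical
models, the decision thresholds, and the design choices behind each step,
and what the synthetic-data validation does and does not demonstrate.

## Homoeolog expression bias

Expression is normalized by total mapped reads: each sample's counts are
scaled by the mean library total over all samples divided by that sample's
total. The mean (rather than the minimum or median) is an arbitrary but
documented reference; any constant gives identical ratios because a
within-sample ratio cancels the factor. Note one consequence we rely on in
tests: total-count normalization is only neutral when most genes are
unbiased, so model-identity checks on all-biased toy data read counts on
the raw scale.

A pair enters the analysis in a group only when both homoeologs have at
least `min_reads = 5` raw reads in every replicate of that group, applied
per group (whether the original filter was per group or joint across groups
is not documented; per group is the weaker, safer reading). Homoeolog
expression bias (HEB) is `log2(R/C)` of replicate-mean normalized counts;
per-replicate ratios are retained for the ratio test. `|log2(R/C)| > 1`
(strictly) is called R- or C-biased; anything nonzero up to 1 is a
"potential" bias; the boundary value 1 itself is potential because the
published rule is a strict inequality. Silencing states are per gene and
group: all replicates zero is silenced, all at least 5 reads is expressed,
anything else indeterminate.

The "in silico hybrid" is the parental reference ratio `P`: the R ortholog
measured in the R-parent samples over the C ortholog in the C-parent
samples, with replicates paired in sample-sheet order. The pairing is
arbitrary; the downstream two-sample test is invariant to it.

## Cis/trans decomposition

The classification rests on the identity `P = cis + trans`, `H = cis`:
cis-regulatory divergence is allele-linked and survives in the hybrid
ratio `H`, while trans-acting divergence equalises in the shared hybrid
nucleus, leaving the difference `T = P − H` as the trans component. Three
tests feed the seven-way call: parental divergence (is `P ≠ 0`?), hybrid
divergence (is `H ≠ 0`?), and the ratio shift (is `T ≠ 0`?). The rule
table is:

| parental | hybrid | shift | category |
|---|---|---|---|
| – | – | – | conserved |
| + | + | – | cis only |
| + | – | + | trans only |
| + | + | + | cis + trans (signs of H and T agree) / cis × trans (oppose) |
| – | + | + | compensatory |
| anything else | | | ambiguous |

Signs use a deterministic tie rule (`+` above 1e-9, `−` below −1e-9, else
zero); a needed-but-zero sign sends the pair to ambiguous.

**Choice of test.** Per-pair two-sample t-tests with three replicates have
about four degrees of freedom and correspondingly poor power (roughly
0.4–0.7 for four-fold effects at depth 100), which makes the classifier
miss most planted cis-only and trans-only architectures. This is the
textbook setting for variance moderation, so `classify_pairs()` defaults to
limma-trend fits across all pairs: one on `log2(count + 0.5)` replicate
values for the parental and hybrid contrasts, one on the per-replicate
log2 ratios for the shift test, each at `p < 0.01`. The moderated path
recovers ≥95% of planted cis-only and trans-only pairs while miscalling
under 5% of conserved pairs (the acceptance script recomputes these
rates). The isolated primitives remain available and unchanged —
`count_diff_test()` is a Welch t-test on `log2(count + 0.5)` with a
fold-change gate `|log2FC| > log2(4)` and a 0.5 pseudocount on means, and
`ratio_diff_test()` is a plain Welch test — and `classify_pairs(method =
"welch")` composes them literally. We do not gate the moderated path on
fold change: with planted effects of 2 log2 units a gate at `log2(4) = 2`
sits exactly on the effect and removes half of all true calls regardless
of depth.

Degenerate zero-variance replicate sets receive a deterministic 1e-9
spread on the log scale before any t-test so the statistic is defined and
identical-input comparisons return p ≈ 1.

**13 directional subpatterns.** Conserved stays whole; the six other
categories each split into `_toR`/`_toC` by the sign of the driving
component — the hybrid ratio `H` for cis-driven categories, the trans
component `T` for trans-only and compensatory (whose `H` is near zero by
construction). A `strong` flag marks pairs with `|P|` or `|H|` above
`log2(4)`, or a methylation difference above 0.3 when one is supplied.
The membership of the 13 labels is an interpretation: only the count and
the thresholds are published.

**Ka/Ks and binary association.** Ka/Ks ratios are consumed as an input
table; per-category summaries use Welch t-tests of cis-only and trans-only
genes against all classified genes. The association between binary gene
sets (e.g. methylation-regulated genes versus cis-only genes) is the phi
coefficient — Pearson correlation of 0/1 indicators — with a
continuity-corrected chi-square p-value; the published phrase "Pearson's
rank correlation" conflates two statistics, and phi is the one defined for
binary indicators.

## DNA methylation

Each cytosine with `k` methylated of `n` total reads is tested against a
null error rate `p0 = 0.01` (bisulfite non-conversion plus sequencing
error; the value is not published, so it is configurable and can be
estimated from non-CpG methylation) with the one-sided upper binomial tail
`P(X ≥ k | n, p0)` — one-sided because only an excess of methylated reads
is evidence of 5mC. Sites need depth > 4X (`n ≥ 5`); Benjamini–Hochberg
adjustment runs over tested sites and calls use FDR < 0.05. On pure-null
data at these depths the procedure makes essentially no calls, so the
observed false-discovery proportion is zero; the mixed null/methylated
simulation in the unit suite is the informative check (FDP ≤ 0.07 at
nominal 0.05, sensitivity > 0.9 at ML 0.8).

Gene-level methylation is summarised over three strand-aware regions — 2 kb
upstream of the TSS, gene body, 2 kb downstream of the TTS — each split
into 20 equal windows ordered 5′→3′ (reversed for minus-strand genes).
Window and region levels are coverage-weighted (`Σk/Σn`) over CpG records
only; CHG/CHH records are parsed and counted but excluded. Empty windows
are missing, not zero.

Region-level differential methylation uses a deliberately simplified DMR
surrogate — a two-sided Fisher exact test on pooled region counts with an
effect gate `|ΔML| > 0.1` at `p < 1e-5` — because the downstream gene
classification only needs a region-level decision, not the two-stage
machinery of dedicated DMR callers. DMG classes use the published
thresholds verbatim: hyper-DMG when the parental ortholog difference
exceeds 0.6 while the hybrid homoeolog difference stays below 0.3;
hypo-DMG when the parental difference is strictly between 0 and 0.6 with
hybrid below 0.2 (the asymmetric 0.2 is implemented as printed; its
rationale is not documented). Methylation-regulated genes (MRGs) require
`|DM| > 0.4`, expression fold change above 4, and discordant signs. All
boundary comparisons are strict.

## Unequal homoeologous recombination

The copy-ratio statistic is `log10((R_reads/R_len)/(C_reads/C_len))` per
pair; states use the printed thresholds `log10(2) = 0.30103` and
`log10(0.5) = −0.30103`, strict on both sides (boundary handling is not
published; strict keeps the balanced call conservative). Zero counts give
sentinels rather than pseudocount ratios — complete homoeolog replacement
is a distinct biological state, and a pseudocount would shrink it into the
callable range with a wrong magnitude; a pseudocount mode (0.5 reads) is
available for noisy data. Segments are maximal runs of at least 3
consecutive map positions whose states all favour the same subgenome
(`R_gain`/`C_absent` toward R, the mirror pair toward C); balanced or
untestable genes and map gaps break runs, and runs never span chromosome
pairs. "Contiguous" means consecutive order in the homoeolog map, not
genomic distance. Segment sets from different samples are compared by
reciprocal ≥50% index overlap.

## TEs, structural variants, and parental divergence

TE density per window is union coverage (never double-counted) divided by
window length; the default window is 100 kb (not published; configurable).
SVs are TE-proximal when strictly closer than 1 kb to the nearest TE.
Because the published figure is ambiguous about whether its t-test compares
classes or tests the correlation, both are computed: the Pearson r between
per-window TE density and SV count with `t = r·sqrt(n−2)/sqrt(1−r²)`, and a
Welch test of SV counts between TE-dense and TE-poor windows split at the
median density. Per-superfamily analyses key on the free-text name column
of the TE intervals. Chromosome-pair summaries report ortholog fractions
and the TE-fraction difference between parents.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions for every recovery property.

* **Genome**: pairs spread evenly over chromosome pairs; gene lengths
  log-uniform 500–5000 bp; intergenic gaps uniform 4500–8000 bp, chosen to
  exceed both 2-kb flanks so adjacent genes' promoter/downstream regions
  never overlap and planted region signals stay gene-exclusive.
* **Expression**: per pair a category is drawn (defaults: 70% conserved,
  10% cis-only, 10% trans-only, 5% cis+trans, 2.5% cis×trans, 2.5%
  compensatory) and effects of ±2 log2 units planted. Parental means split
  a shared baseline symmetrically (`b·2^{±P/2}`) so total expression is
  category-independent; F1 uses `H = cis`; F22 uses
  `H′ = cis·(1 − 0.5)`, modelling the observed generational decay of bias
  as tunable trans compensation rather than a hard-coded outcome. Counts
  are negative binomial with a single shared dispersion (0.05) around a
  log-normal baseline (median 100, sdlog 0.5). With equal cis and trans
  magnitudes, a planted cis×trans architecture is mathematically identical
  to compensatory (`P = 0`), so that category is only recoverable when the
  two effect sizes differ — a degeneracy of the design, not a classifier
  fault.
* **Methylation**: region levels are Beta(2,2); pairs carrying a planted
  parental difference draw the low parent from a Beta(2,2) truncated to
  `[0, 1 − ΔML]` so the planted shift is realized exactly; hybrids sit at
  mid-parent ± half the planted hybrid difference. Per cytosine, depth is
  Poisson(30) and methylated reads binomial with probability
  `ML + p0`.
* **Copy number**: read counts are Poisson with mean
  `depth·copies/2·length/1000`; planted segments set (r, c) copies,
  including complete replacement (0, 4), which exercises the sentinel
  policy downstream.
* **SVs**: per-window counts are Poisson with log-intensity
  `α + slope·TE_density`, α calibrated so the mean is 2 per window.

Every generator is a pure function of (params, seed). What passing
recovery tests show is that the pipeline's decisions are correct when the
data match these assumptions; they do not show robustness to features of
real data the generator omits — per-gene dispersion, mapping bias between
subgenomes, coverage heterogeneity along chromosomes, non-CpG methylation
structure, or correlated replicates.

## Problem sizes and runtimes

The validation suite uses 1,000 pairs for cis/trans recovery, a
10,000-gene track with ten planted segments for recombination recall,
10^5 cytosines for the null FDR check, and ~400 windows of 20 kb for the
TE–SV association; the default end-to-end dataset is 500 pairs on two
chromosome pairs. These sizes put every estimate's Monte-Carlo error well
inside the decision margins while keeping a full run in seconds.

## Known limitations

* The count-table and cytosine-table inputs are taken as given; alignment,
  counting, and bisulfite processing are upstream.
* Recombination segments are called from depth ratios only; breakpoint
  evidence from split reads or an SV caller is not integrated, so event
  counts are not comparable to callers that merge both evidence types.
* No multiple-testing correction is applied across pairs in the
  classification (matching the published raw `p < 0.01` usage); a BH
  option exists but changes the meaning of the thresholds.
* The 13-subpattern membership and the direction rule for its splits are a
  documented interpretation of an underspecified construction.
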