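---
title: "Inferring a direct regulatory network from binding and knockout expression"
author: "bindxpress"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Inferring a direct regulatory network from binding and knockout expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindxpress)
```

# The problem

A transcription factor (TF) typically binds far more genes than it
regulates. Given in vivo binding maps (ChIP-seq peak calls obtained under
two different tissue-specific driver conditions of a tagged TF) and the
transcriptional consequences of removing the TF (per-tissue
differential-expression tables from a knockout-versus-wild-type single-cell
comparison), the question is which bound genes are *functional* targets —
and what distinguishes them.

bindxpress implements that integration as a deterministic, fully testable
pipeline. The motivating biological setting is an embryonic
high-secretion tissue (a salivary-gland-like focal tissue) whose master
regulator boosts secretory pathway component genes (SPCGs), but every stage
is generic: any TF with two driver-restricted peak sets and a knockout DE
table fits the contracts.

# The model and its stages

## Tissue-specific binding

Each driver condition yields one narrowPeak set. Binding specific to the
tissue where *both* drivers are active is defined as the peaks of the first
set that share at least one base with any peak of the second
(`intersectKeepA`). The original first-set entries are kept unmodified and
deduplicated — the intersection restricts, it does not fragment. A
fragment-free definition keeps peak identity stable, so every downstream
window and assignment refers to a real called peak.

## Peak-to-gene assignment

The peak center is `floor((start + end) / 2)` in the 0-based BED frame — a
deterministic choice for odd widths that matches common interval tooling.
The narrowPeak summit offset is deliberately ignored: the assignment rule
is defined on the interval center.

Each gene contributes one anchor, its strand-aware 5′-most transcription
start site: the minimum transcript start on the plus strand, the maximum
transcript end on the minus strand. For each peak, the nearest TSS at or
left of the center and the nearest TSS right of it are assigned when the
distance is *strictly* less than 1 kb, so each peak maps to 0, 1, or 2
genes. Left/right is genomic position around the center, not gene strand;
strand is consumed only in deriving the TSS. A TSS exactly at the center
counts once, as the left-side candidate at distance 0. Equidistant ties on
one side are broken by lexicographically smaller gene identifier, with a
warning — deterministic and auditable, if biologically arbitrary.

Coordinates live in `GRanges` (1-based, closed) inside the package; BED
and narrowPeak files (0-based, half-open) are converted at the parser
boundary and back at the writer. The center and minus-strand TSS rules are
algebraically identical in both frames (`center1 = floor((start0 + end0)/2)
+ 1`), and boundary unit tests pin the equivalences.

## Target classification

All threshold inequalities are strict, exactly as the rules are stated;
boundary values (logFC of −0.15, p of 0.05, fold change of −1.25, 10 %)
are excluded, and a dedicated test sweeps logFC through
{−0.151, −0.150, −0.149} and friends.

A gene is **activated** when any of three evidence routes holds:

* focal-tissue `logFC < −0.15` and `p < 0.05` (scRNA route);
* membership in a curated in-situ-validated list;
* microarray `fold change < −1.25` and `p < 0.05`, *and* the gene is
  expressed in more than 10 % of wild-type focal cells *and* shows
  `logFC < 0` in the focal DE table. A microarray gene absent from the DE
  table fails this route closed (and is logged): the expression filters
  cannot be evaluated, so the evidence is not admitted.

**Repressed** genes use only the scRNA route (`logFC > +0.15`,
`p < 0.05`): bulk up-regulation signals from whole-embryo assays are too
contaminated by other tissues to be trusted for repression.

Two deliberate interpretations, both switchable or explicit in the API:

* p-values are used **unadjusted** by default (`adjustP = FALSE`), because
  the classification rule is stated on plain p-values; a
  Benjamini–Hochberg mode is provided for sensitivity analyses.
* a gene reaching the activated set through the in-situ or microarray
  route while simultaneously meeting the scRNA repression rule is a
  **conflict**: it is excluded from both sets and reported
  (`resolveCallConflicts`). Silent precedence for either call would bias
  the network fractions in an undocumented direction.

The **unchanged** class is the `unchangedN` (default 150) genes with the
smallest *absolute* logFC — "least differentially expressed" means closest
to zero, not most negative. Ties take the larger p-value first (the less
significant gene is the more plausibly unchanged one), then the gene
identifier. The pipeline excludes activated/repressed calls from the pool
before selecting, so the three classes are disjoint by construction.

`buildNetwork` intersects bound with the regulated sets and reports every
summary as a numerator/denominator pair; an empty bound set yields `NA`
sentinels, never a silent 0.

## Overlap analytics

`sharedFraction` measures how much of the focal tissue's
down-(or up-)regulated set recurs in at least one other tissue;
`vennCounts` gives exclusive region counts for up to three sets (counts sum
to the union size); `celltypeSpearman` rank-correlates matched wild-type
and mutant average expression profiles with average-rank ties, over the
genes expressed (mean > 0) in at least one genotype for that cell type,
returning `NA` below 3 shared genes. Gene universes are taken as the union
of genes each method reports; a gene absent from a method is "not called",
not missing.

## Motif enrichment

Sequence windows of center ± 250 bp (clipped at chromosome ends) are
extracted per regulatory class from the intersected peaks. Discovery is an
explicitly simplified discriminative search:

1. every exact word of length 3–8 present in a positive window (either
   strand) is counted by per-sequence presence — one sequence, one count,
   palindromes once;
2. enrichment against the control windows is scored by the one-sided
   hypergeometric tail (Fisher), and an E-value multiplies the p by the
   number of distinct words actually tested in the run;
3. the top seed is generalized by a greedy hill-climb over single-position
   replacements with 2- or 3-letter IUPAC codes, accepting only
   p-improving moves — the result never scores worse than its seed.

This is *not* DREME: there is no heuristic word sampling and no sequential
motif erasure. The control defaults to the bound-unchanged windows (the
natural within-experiment contrast); a dinucleotide-preserving shuffle
(`dinucleotideShuffle`, Altschul–Erickson style) is provided as an
alternative control. `pwmCompare` scores a query against a PWM library by
the best mean per-column Pearson correlation over all ungapped offsets and
both orientations with at least 4 aligned columns, and
`classUniqueMotifs` reports words significant (E-value below threshold) in
exactly one class, comparing words by IUPAC set equivalence.

## Preranked GSEA

Classic weighted Kolmogorov–Smirnov running sum: hits increment by
`|stat|^weight` normalised by the in-set total, misses decrement by
`1/(N − Nh)`; the enrichment score is the running-sum value of maximum
absolute magnitude (+1/−1 analytic extremes for a single-gene set ranked
first/last). Sets are filtered to 10–500 genes *after* intersection with
the ranked universe. The null is `nPerm` (default 1000) random same-size
gene draws under a caller-supplied seed; NES divides by the mean absolute
null score of matching sign and `p = (1 + #extreme) / (1 + #same-sign)`
never returns zero. BH adjustment runs across retained sets. This plain
permutation estimator stands in for adaptive multilevel p-value schemes;
enrichment scores agree exactly with the standard definition (and are
cross-checked against an independent implementation in the tests),
p-values agree approximately, with granularity `1/(nPerm + 1)`. Tied
statistics keep stable input order with a warning. The pipeline ranks
genes by −logFC, so activated genes sit at the top of the ranking.

# The synthetic-data generator

`generateBundle(syntheticConfig(seed))` emits the complete input bundle
plus a `truth.json`. What it emulates — and what it does not — determines
what a green test suite proves.

**Reference conditions** (chosen once; all configurable):

| parameter | default | why |
|---|---|---|
| genome | 3 chromosomes × 500 kb, i.i.d. uniform ACGT | smallest genome that spaces 200 genes far enough apart that no peak can sit within 1 kb of a neighbouring TSS; uniform background makes Fisher calibration analytically checkable (a `gcBias` knob exists for robustness runs) |
| genes | 200, 1–3 transcripts, random strand | multi-transcript models exercise the 5′-most rule |
| true targets | 30, of which 70 % activated | yields 21 activated / 9 repressed |
| decoy bound genes | 40 | bound-but-unregulated, the "binding exceeds regulation" regime |
| peak width / jitter | 200 bp, sd 150 truncated at ±700 | truncation guarantees the planted <1 kb rule; the second driver's peak is re-jittered within half a width so the two sets always overlap on planted genes |
| planted motif | `TGACGTCA` | a CRE-like placeholder word — *not* any experimentally determined consensus; planted once in the ±250 bp window of every activated gene's peak |
| effect size | logFC magnitude 0.5 (× U(1, 1.8)) | comfortably beyond the 0.15 threshold so truth is recoverable; the config refuses effect sizes ≤ 0.15 |
| logFC noise | sd 0 | noise is an explicit robustness knob, not a default condition |
| tissues | 5, targets shared with the focal tissue at rate 0.79 | emulates the ~72–79 % cross-tissue overlap regime of multi-tissue knockout comparisons |
| evidence routes | 10 % of activated genes in-situ-only, 10 % microarray-only | exercises the three-route union: those genes keep focal logFC in (−0.15, 0) and are reachable only through their side evidence |

Decoy bound genes have focal logFC clamped inside (−0.149, +0.149), so
they can never be called regulated; driver-specific peaks are placed in
gene-free territory so they always drop out at intersection. The
microarray table includes passing-but-blocked background entries (fold
change and p pass, focal logFC ≥ 0) to exercise the direction filter.

**What it does not emulate:** read-level sequencing noise, peak-calling
artefacts, chromatin state, correlated gene programs, mappability, GC
composition of real promoters, or realistic p-value/logFC joint
distributions. Passing the planted-truth tests therefore demonstrates the
*correctness of the integration logic and its boundary behaviour*, not
performance on real ChIP-seq/scRNA-seq data.

All generator randomness flows through one seed; the global RNG state is
saved and restored, and two calls with the same configuration produce
byte-identical files.

# Numerical and design choices

* Strict inequalities everywhere thresholds are stated; boundary sweeps in
  the tests pin them.
* Peak center `floor((start+end)/2)`; summit offsets ignored.
* Degenerate inputs return sentinels, not zeros: empty bound set → `NA`
  fractions; empty focal set → `NA` shared fraction; fewer than 3 shared
  genes → `NA` Spearman rho.
* Zero-variance PWM column pairs correlate 1 when identical, 0 otherwise
  (plain Pearson is undefined there).
* `wordEnrichment` truncates `kMax` to the shortest sequence with a
  warning; the E-value correction factor is the number of words actually
  tested in that run, so E-values are comparable only within a run.
* GSEA p-values use the add-one estimator and are bit-reproducible for a
  fixed seed; ties in ranking statistics are kept in stable input order
  with a warning.
* Problem sizes in the test suite (bundles of 50–200 genes, 100–1000
  permutations, 20-seed replicates, 200-replicate calibrations) are the
  package's reference verification sizes: large enough for stable
  averages, small enough to run routinely.

# Known limitations

* Gene identifiers are matched as exact strings; no symbol aliasing.
* The logFC scale (natural log vs log2) is taken as-is from the input
  table; thresholds apply to whatever scale the table carries, so tables
  produced under a different convention need rescaling upstream.
* The motif stage reports words, not position weight matrices learned by
  EM; `iupacToPwm` bridges to PWM comparison but carries no positional
  information content beyond the IUPAC sets.
* The permutation GSEA cannot resolve p-values below `1/(nPerm + 1)`.
* `vennCounts` is limited to three sets by design; larger comparisons
  should be decomposed pairwise.

# Session info

```{r}
sessionInfo()
```
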