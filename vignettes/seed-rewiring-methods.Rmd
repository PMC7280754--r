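---
title: "Methods: isomiR seed shifts and target-network rewiring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomiR seed shifts and target-network rewiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedshift)
```

## The problem and the model

Mature miRNAs are produced with heterogeneous ends: alternative and
imprecise Drosha/Dicer cleavage yields isoforms (isomiRs) whose 5' and/or
3' ends deviate from the annotated mature by a few nucleotides. Because
target recognition is dominated by the seed — nucleotides 2–8 of the mature
sequence — a 5' offset rewrites the seed heptamer and can redirect the
molecule to a substantially different set of mRNAs, while 3'-only isoforms
keep the annotated seed and, to first order, the annotated target set.
Standard quantification pipelines collapse all isoforms onto the annotated
mature and discard exactly this signal.

`seedshift` treats each distinct (seed, 5'-offset) pair of a locus arm as a
*seed variant* and asks, per variant:

1. Is the variant deregulated between tumor and normal samples?
2. Which mRNAs does its seed reach (canonical 8mer / 7mer-m8 / 7mer-A1
   sites in 3'UTRs), and do expression data support repression (opposite
   deregulation plus negative Spearman correlation)?
3. Does a shifted ("novel") seed's target set diverge from the annotated
   seed's set beyond what same-sized random sets would share?
4. Do the gained/lost targets concentrate in annotated gene classes, and do
   variant-defined patient or cell-line groups differ in survival or drug
   response?

### The divergence statistic

For a novel seed with $N_x$ targets, its annotated seed with $N_y$ targets,
$N_{xy}$ shared, out of a universe of $N$ genes, the divergence p-value is
the lower tail of the hypergeometric distribution evaluated just below the
observed overlap:

$$p_{x,y} = F(N_{xy}-1 \mid N, N_x, N_y)
  = \sum_{t=0}^{N_{xy}-1}
  \frac{\binom{N_x}{t}\binom{N-N_x}{N_y-t}}{\binom{N}{N_y}}.$$

A small $p$ means the two sets share *fewer* targets than random sets of
those sizes would. `overlap_pvalue()` accumulates the sum in log space
(`lchoose` + log-sum-exp); terms outside the hypergeometric support
contribute zero. Two properties deserve emphasis:

* $N_{xy} = 0$ gives the empty sum, exactly $p = 0$, for *any* set sizes.
  Small random sets from a large universe are usually disjoint, so near-empty
  sets would be flagged spuriously. `divergence_scan()` therefore tests only
  comparisons where both sets have at least `min_set_size` (default 5)
  targets, and even so the statistic should be read as "shares nothing
  detectable", not as calibrated evidence, when target sets are small
  relative to the universe.
* The universe $N$ is ambiguous in principle. The default is every gene with
  a UTR in the input collection; restricting to the union of predicted
  targets across seeds is a caller choice (pass that union as `universe`).
  Larger universes make disjointness less surprising in absolute terms but
  do not change the $N_{xy}=0$ edge.

P-values are BH-adjusted across all novel-vs-annotated comparisons and
flagged divergent at FDR < 0.05; both the raw p and the FDR are reported.

### Decision thresholds

All thresholds sit in `run_config()` and are echoed into the run summary:

| quantity | rule | default |
|---|---|---|
| deregulation | \|log2FC\| > `lfc_threshold` **and** BH-adjusted p < `de_alpha` | 1.5, 0.05 |
| detection | raw count > 0 in ≥ `detection_fraction` of samples | 0.5 |
| abundance | max RPM ≥ `min_rpm`, baseMean ≥ `min_baseMean` ("not less than": boundary kept) | 50, 500 |
| correlation screen | rho < 0, BH FDR < `screen_alpha`, both groups ≥ `screen_min_n` | 0.05, 50 |
| divergence | BH FDR < `divergence_alpha`, both sets ≥ `min_target_set` | 0.05, 5 |
| drug response | \|DR\| > `dr_threshold` **and** p < `dr_alpha` | 0.1, 0.05 |

## Differential expression: a deliberately lightweight stage

Counts are normalised by median-of-ratios size factors (the same estimator
as `DESeq2::estimateSizeFactorsForMatrix`, against which `size_factors()`
is cross-checked in the tests); the fold change is
`log2((mean_T + 0.5) / (mean_N + 0.5))` on group means of normalised
counts; the p-value is a two-sided Wilcoxon rank-sum test per feature; BH
controls the FDR. No dispersion shrinkage, covariates or batch correction
are attempted: the stage exists to apply the thresholds above to matrices
whose planted effects are large (|log2FC| = 2.5 at dispersion 0.1), and its
acceptance standard is planted-effect recovery, not numerical equality with
any NB-GLM implementation.

Two numerical notes. The 0.5 pseudocount keeps zero group means finite and
biases very-low-abundance fold changes toward zero — harmless above the
baseMean ≥ 500 filter. And median-of-ratios factors are defined only up to
the geometric-mean normalisation: scaling one sample's counts by $c$
multiplies its factor by $c$ *relative to the other samples* (absolutely,
by $c^{(n-1)/n}$), so normalised counts are depth-invariant up to one
global constant, which cancels in fold changes and rank tests.

## Target prediction

`site_patterns()` builds the three canonical site types on the target
strand: 7mer-m8 = reverse complement of the seed; 8mer = 7mer-m8 followed
by `A`; 7mer-A1 = reverse complement of miRNA positions 2–7 followed by
`A`. `scan_sites()` reports every overlapping occurrence with deterministic
precedence 8mer > 7mer-m8 > 7mer-A1 at overlapping loci, so a planted 8mer
is never double-reported as its internal 7mers. Context-style scoring,
conservation and 3'-supplementary pairing are out of scope; stringency is
controlled instead by the site-type filter (`build_target_sets()` counts
8mer and 7mer-m8 sites by default; add `"7mer-A1"` to lower it). Variants
sharing a seed string — in particular 3'-only isoforms — share one target
set by construction.

## What the synthetic data emulate

`simulate_dataset()` builds the full study with a plant ledger:

* **Repertoires** — per-locus canonical template plus Poisson(3) extra
  templates with independent 5' (p = 0.2) and 3' (p = 0.6) end shifts of
  ±1–2 nt, 3' variation deliberately the more frequent mode; plus a focal
  locus carrying the annotated mature, a +1 seed-shifted isomiR and a
  3'-only isomiR. The focal reference is redrawn until the two seeds' site
  patterns contain no substring of each other; otherwise a planted site for
  one seed would be an unavoidable off-target match of the other and the
  UTR sampler below could never satisfy its guarantee.
* **Counts** — NB(mean = $\mu_i s_j g_{ij}$, dispersion 0.1), $\mu_i$
  log-uniform over [100, 2000], size factors $s_j$ log-uniform over
  [0.5, 2], symmetric group multiplier $2^{\pm \mathrm{log2FC}/2}$ for
  planted features. Defaults: 60 tumor / 60 normal samples (so the n ≥ 50
  screen gate is exercised), planted |log2FC| = 2.5.
* **UTRs** — 200 genes × 500 nt; every planted (gene, seed, site type) is
  embedded at a recorded position and rejection sampling guarantees the
  scan of any monitored seed recovers exactly the ledger.
* **Coupling** — planted isomiR:mRNA pairs through a Gaussian copula at
  Pearson $2\sin(\pi\rho/6)$ so the *Spearman* correlation hits the target
  $\rho$ (default −0.6) without constraining the NB marginals.
* **Survival** — exponential event times, hazard ×3 (default) above the
  expression median; censoring is per-subject Bernoulli(0.2) with censor
  time uniform on (0, event time) — exact rate control, independent of
  group under the null.
* **Drug response** — Gaussian sensitivities around 0.4 (sd 0.1), +0.2 for
  the shifted-seed group, clipped to [0, 1].

What it does **not** emulate: TCGA library-size and batch structure, tumor
purity, correlated miRNA families, UTR base composition and length
heterogeneity, isomiR-calling noise, or competition between co-expressed
miRNAs for shared targets. Passing tests therefore demonstrate that the
statistical machinery recovers known structure at realistic effect sizes
and sample counts — not that real-data preprocessing artifacts are handled.

## Other design choices

* **Coordinates** are 1-based inclusive in the dialect
  `assembly:chrom:start-end:strand`; parse → format is bit-exact. On the
  minus strand the genomic end is the transcript 5' end, so
  `classify_shift()` swaps start/end roles; this convention is fixed by
  tests on both strands.
* **Multicopy isomiRs** (identical sequence from different loci) collapse
  to one representative — the lexicographically smallest locus id — so
  expression is kept without double counting; `mode = "drop_all"` removes
  them entirely for the strictest reading of "eliminated".
* **Trend test** — seed shifts form ordered groups, so the trend primitive
  is Jonckheere–Terpstra; the default p-value is a seeded two-sided
  permutation (valid under ties), with the large-sample normal
  approximation (no tie correction) as an option.
* **Median split** — samples strictly above the median are "high"; ties at
  the median go "low"; fewer than two distinct values is an error rather
  than an arbitrary split.
* **Drug-response grouping and sign** — cell-line groups are defined by the
  isomiR's expression median, mirroring the survival design; DR = mean
  sensitivity of the shifted/high group minus the comparison group on a
  pre-scaled [0, 1] sensitivity measure (how any external measure is scaled
  is the caller's responsibility); positive DR is called "resistant",
  negative "sensitive", and the conjunction |DR| > 0.1 with p < 0.05
  (Wilcoxon) is required for any call.
* **Wilcoxon switching** — exact enumeration when the smaller group has ≤ 10
  observations and no ties; otherwise normal approximation with tie and
  continuity correction.

## Problem sizes in the checks

The test suite and the acceptance script size their simulations as: 300
isomiRs with 30 planted effects at 30/30 samples for fold-change recovery;
20 planted couplings against 200 decoys at 60/60 samples for the screen;
the default study (10 background loci + focal locus, 200 genes) for
end-to-end rewiring; 100 simulations for log-rank power and 200 for type-I
error at 100/100 patients; 100 null datasets for the drug-response call
rate; exhaustive enumeration up to N = 25 for the divergence formula and
1,000 random 500-nt UTRs × 20 seeds for the scanner. These sizes give
Monte-Carlo error comfortably below the decision margins being verified.

## Known limitations

* The divergence p-value is a one-sided "fewer shared than expected" tail;
  it does not measure *how* the sets differ, and at $N_{xy}=0$ it is 0
  regardless of power — interpret together with the set sizes it reports.
* The DE stage's rank test loses power relative to NB-GLMs at small n and
  does not model dispersion trends; it is intentionally not a DESeq2
  substitute at marginal effect sizes.
* Target prediction is sequence-only; absence of a seed site is treated as
  absence of targeting.
* The log-rank test is unadjusted (no covariates) and the median split
  discards dose information.
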