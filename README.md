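# seedshift

IsomiR seed-shift classification and target-network rewiring analysis.

## The problem

Mature miRNAs are sequenced as families of isoforms (isomiRs) whose 5' and
3' ends deviate by a few nucleotides from the annotated mature. Because
targeting is governed by the seed (mature nucleotides 2–8), a 5'-shifted
isomiR carries a *novel seed* and can repress a different set of mRNAs,
while 3'-only isoforms keep the annotated seed. Pipelines that collapse all
isoforms onto the annotated miRNA erase this rewiring. `seedshift`
implements the downstream analysis for seed-shifted isomiRs end to end, for
transcriptomics analysts working from quantified isomiR tables (coordinate
dialect `hg38:chr22:46112751-46112773:+`), mRNA count matrices, 3'UTR
FASTA, GMT gene sets, and clinical / drug-sensitivity tables.

## What it computes

* **Seed variants** — coordinate parsing, strand-aware 5'/3' offset
  classification, one variant per distinct (seed, 5'-offset) within ±5 nt,
  multicopy collapse.
* **Deregulation** — median-of-ratios normalisation, detection/RPM/baseMean
  filters, per-feature Wilcoxon + BH; significant iff |log2FC| > 1.5 and
  adjusted p < 0.05.
* **Targets** — canonical 8mer / 7mer-m8 / 7mer-A1 seed-match scanning of
  UTRs with 8mer-first precedence.
* **Screening** — opposite-deregulation candidates, then Spearman rho < 0
  with FDR < 0.05 and ≥ 50 samples per group.
* **Divergence** — for a novel seed *x* vs its annotated seed *y*, the
  lower-tail hypergeometric CDF on the shared-target count,

  p(x,y) = F(Nxy − 1 | N, Nx, Ny) = Σ_{t=0}^{Nxy−1} C(Nx,t) C(N−Nx, Ny−t) / C(N, Ny),

  BH-adjusted across comparisons; target **gain/loss** partitions; ORA
  enrichment of gained/lost sets; rewired bipartite networks as
  Cytoscape-ready edge lists.
* **Clinical endpoints** — median-split log-rank survival and drug-response
  calls (|DR| > 0.1 and p < 0.05).
* **Synthetic data** — every input with planted ground truth (NB counts
  with planted log2FC, UTRs with planted sites, copula-coupled mRNA,
  exponential survival, shifted drug sensitivities) plus a plant ledger.

## Worked example

```r
library(seedshift)

parse_isomir_coordinate("hg38:chr22:46112751-46112773:+")
#> <genomic_span> hg38:chr22:46112751-46112773:+ (23 nt)

cfg <- run_config(simulation = simulation_config(rng_seed = 1),
                  outdir = tempfile())
res <- run_pipeline(cfg)
res$dataset
#> <seedshift_dataset> 34 isomiR templates / 11 loci; 120 samples;
#>                     200 UTRs; 20 planted sites

subset(res$de_variant, significant & grepl("focal", feature_id))
#>       feature_id baseMean   log2FC      p_value   adjusted_p direction significant
#> 1 mir-focal-5p+0 836.3097 2.475156 3.556571e-21 8.622436e-21        up        TRUE
#> 2 mir-focal-5p+1 543.8476 2.484919 3.556571e-21 8.622436e-21        up        TRUE

res$divergence[res$divergence$tested, ]
#>           seed_x         seed_y Nx Ny Nxy p_value fdr divergent
#> 1 mir-focal-5p+1 mir-focal-5p+0 10 10   0       0   0      TRUE

lengths(gain_loss(res$target_sets[["mir-focal-5p+1"]],
                  res$target_sets[["mir-focal-5p+0"]]))
#> shared gained   lost
#>      0     10     10

res$network
#> <rewired_network> 21 edges, 20 genes (annotated-specific: 10, novel-specific: 10)

res$drug_response
#>     drug        DR      p_value      call
#> 1 drug_1 0.1904074 4.370281e-10 resistant
```

Reading this: both focal variants recover their planted +2.5 log2FC
(estimates 2.48 / 2.48); the +1-shifted variant's 10 planted targets are
disjoint from the annotated seed's 10, so the divergence test flags it
(FDR < 0.05) and the gain/loss partition is 10 gained / 10 lost / 0 shared
— exactly the plant ledger. The 3'-only isomiR shares the annotated seed
and is folded into variant `mir-focal-5p+0` (never tested as novel). All
21 screen-passing isomiR:mRNA pairs become network edges, and the drug
table's planted +0.2 sensitivity shift is called `resistant`
(DR = 0.19, p = 4.4e-10).

A command-line front-end with the same defaults lives at
`inst/scripts/seedshift-run.R`.

## Documentation

The methods vignette (`vignettes/seed-rewiring-methods.Rmd`) describes the
model, every threshold with its default, what the synthetic data do and do
not emulate, numerical edge cases (the Nxy = 0 divergence edge, minus-strand
offset conventions, median tie policy), and known limitations.
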