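# epistress

Integrative analysis of how microRNA targeting and DNA methylation
jointly regulate stress-responsive genes over a repeated-stress time
course.

## The problem

Organisms facing recurrent environmental stress (the motivating system is
an invasive marine invertebrate under repeated hyperosmotic challenge)
adjust gene expression through several epigenetic layers at once. Two of
the fastest are post-transcriptional repression or activation by miRNAs
and pre-transcriptional modulation by cytosine methylation. Given
time-course multi-omics data — mRNA and miRNA counts plus per-CpG
bisulfite calls across sampling points 0/24/48/96/120/144 h with
replicate counts 6/4/6/4/4/3 (first stress S1, recovery R, second stress
S2) — the questions are:

* which functional (osmotic-strategy) genes are regulated by miRNAs,
  which by differential methylation, and which by both, at each sampling
  point;
* whether genes under dual regulation are more frequent than chance
  ("non-random co-regulation");
* whether miRNA-targeted genes are structurally depleted of methylation
  (lower methylation levels, fewer methylation-capable CpG sites); and
* whether dual regulation amplifies expression changes.

`epistress` implements the full decision chain behind those questions as
a tested R package in Bioconductor style (GRanges/SummarizedExperiment
containers, S4 classes for the central objects).

## The statistics at the core

* **Differential entities.** A gene or miRNA is differential at contrast
  (0 h, *t*) when |log2FC| > 1 and BH-adjusted p < 0.05 (both strict).
  Statistics tables from any external caller are first-class input; a
  built-in plain test (median-of-ratios normalisation, Welch t on
  log2 counts) serves simulated data.
* **Target pairs.** A (miRNA, gene) pair is a true target when both
  prediction tools report it with duplex energy ≤ −20 kcal/mol. Binding
  sites are assigned to 5′UTR/CDS/3′UTR by maximal overlap in transcript
  coordinates, and every pair carries the Pearson correlation of the two
  per-time mean expression profiles.
* **DMSGs.** A differentially methylated CpG (pooled two-sided Fisher
  exact test per site, |Δ| ≥ 25 percentage points, q < 0.01,
  coverage ≥ 10) maps to a gene when it falls in the gene body (TSS–TES)
  or promoter (2000 bp upstream of the TSS, strand-aware); such genes are
  DNA methylation-related stress-responsive genes.
* **Dual-regulation permutation test.** With n_A miRNA-regulated and
  n_B methylation-regulated genes in a universe of N functional genes,
  each of 1000 iterations redraws both sets uniformly without
  replacement and records the overlap; the empirical p for the observed
  overlap k is (1 + #{null ≥ k}) / (iterations + 1). The null is
  hypergeometric, which the test suite verifies against the exact pmf.
* **Structural complementarity.** Per time point, a two-sided Wilcoxon
  rank-sum test compares gene-level methylation (unweighted mean of
  pooled per-site rates over promoter ∪ gene body) between miRNA-targeted
  and non-targeted genes, plus one comparison of per-gene CpG site
  counts, and |log2FC| contrasts between regulation-mode groups.

A parameterised simulator (`simConfig()` / `generateBundle()`) emits a
complete bundle — GFF3 gene models, count tables, sample sheet, two
decoy-laden prediction files, per-sample CpG tables, functional list —
with truth tables for every planted effect, so the whole pipeline is
testable without any download.

## Worked example

```r
library(epistress)

cfg <- simConfig(nGenes = 300, nMirnas = 40,
                 fracTargeted = 0.25, fracDmGenes = 0.12, rhoDual = 3)
bundle <- generateBundle(cfg, seed = 42)
res <- runIntegration(bundle$catalog, bundle$geneCounts, bundle$mirnaCounts,
                      bundle$sheet, bundle$predictionsA, bundle$predictionsB,
                      bundle$methTables, bundle$functional)
res$permutation
```

```
PermutationResult: N = 180, nA = 45 (miRNA), nB = 24 (methylation)
  observed overlap = 19; null mean = 6.03 over 1000 iterations
  empirical p = 0.000999 (add-one convention)
```

The planted three-fold co-regulation enrichment (`rhoDual = 3`) is
detected: 19 dually regulated genes against a null expectation of about
6, empirical p = 1/1001, the smallest value 1000 iterations can return.

```r
subset(res$mode_proportions, time_h == 24)
```

```
 time_h             mode count proportion n_none
     24       mirna_only    15       0.60     33
     24 methylation_only     2       0.08     33
     24             dual     8       0.32     33
```

Among functional genes differentially expressed at 24 h that carry any
regulatory evidence, 60% are explained by miRNA targeting alone, 8% by
methylation alone and 32% by both (the generator's defaults plant miRNA
dominance; `n_none` counts differential genes with no evidence).

```r
res$complementarity$levels[1, c("time", "mean_targeted", "mean_other", "p", "stars")]
```

```
 time mean_targeted mean_other            p stars
    0     0.1712021  0.2107821 5.852412e-05  ****
```

At 0 h, miRNA-targeted genes average a methylation level of 0.17 versus
0.21 for non-targeted genes (rank-sum p ≈ 6e-5) — the planted
structural depression of 0.035 recovered from the beta-binomial CpG
counts.

```r
truthRecoveryReport(bundle, res)$mode_agreement
#> [1] 0.911
```

91% of per-gene regulation-mode calls match the planted truth.

## Layout

* `R/` — annotation (GFF3 gene models, promoter/gene-body/compartment
  assignment), stats primitives, differential expression, targeting,
  methylome, integration, simulator, pipeline orchestration.
* `inst/extdata/table1_dmsgs.tsv` — packaged table of 22 published DMSG
  records used by `summarizeTable1Fixture()`.
* `vignettes/integrative-stress-regulation.Rmd` — the methods vignette:
  model assumptions, parameter choices, simulator design, limitations.
* `tests/testthat/` — unit, property and acceptance tests with
  hand-coded statistical oracles.
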