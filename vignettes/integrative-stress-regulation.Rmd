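---
title: "Methods: integrating miRNA targeting and DNA methylation over a repeated-stress time course"
author: "epistress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating miRNA targeting and DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistress)
```

## The analytical model

`epistress` asks how two epigenetic layers — post-transcriptional
regulation by miRNAs and cytosine methylation — divide the work of
regulating stress-responsive genes across a repeated-stress design:
six sampling times (0, 24, 48, 96, 120, 144 h) spanning a first stress
phase (S1: 24–48 h), a recovery phase (R: 96 h) and a second stress
phase (S2: 120–144 h), with replicate counts 6/4/6/4/4/3 after quality
control.

The chain of inference is deliberately simple and fully explicit:

1. **Differential entities.** For every contrast — each later time
   against 0 h, plus 96 h against 120 h and against 144 h — a gene or
   miRNA is *differential* when strictly |log2FC| > 1 and strictly
   BH-adjusted p < 0.05. These thresholds are the package defaults
   (`lfcMin`, `alpha`) and are applied to whatever statistics table is
   supplied; the analysis begins at the thresholds, not at any
   particular count model.
2. **Target pairs.** Predictions from two independent tools are reduced
   to (miRNA, gene) pairs present in *both* with duplex energy
   ≤ −20 kcal/mol in each source. A pair is *active* at time *t* when
   both its miRNA and its gene are differential at the 0-vs-*t*
   contrast — the gene is then a differentially expressed target gene.
3. **DMSGs.** Per CpG site, group counts are pooled and compared by a
   two-sided Fisher exact test; sites with |difference| ≥ 25 percentage
   points and BH q < 0.01 at coverage ≥ 10 are differential. A gene
   containing such a site in its promoter or gene body is a DNA
   methylation-related stress-responsive gene for that contrast.
4. **Regulation modes.** Each functional gene differential at *t* is
   classified by the 2×2 evidence table: miRNA-only, methylation-only,
   dual, or none.
5. **Non-randomness of dual regulation.** A Monte-Carlo permutation
   test redraws both regulated sets uniformly without replacement from
   the functional universe at each of 1000 iterations and compares the
   observed overlap with the null overlaps.
6. **Structural complementarity.** Wilcoxon rank-sum comparisons of
   gene-level methylation (per time point) and of per-gene CpG counts
   between miRNA-targeted and non-targeted genes, and of |log2FC|
   between mode groups.

## Coordinate and interval conventions

Internally all intervals are GRanges/IRanges, i.e. 1-based closed — the
Bioconductor convention — so standard overlap machinery applies
unchanged. External dialects at the boundary:

* GFF3 in and out is 1-based closed; the writer reproduces input
  coordinates exactly (round-trip tested).
* CpG site tables are 1-based positions.
* Target-prediction tables carry transcript-coordinate intervals as
  0-based half-open (`t_start`, `t_end`), converted on use.

The **promoter** is the 2000 bp upstream of the TSS *in transcription
orientation*: `[tss-2000, tss-1]` on the + strand, `[tes+1, tes+2000]`
in genomic coordinates on the − strand, clipped at contig boundaries.
Whether promoter windows should be strand-aware is genuinely open for
data whose annotation conventions are unknown, so
`promoterStrandAware = FALSE` switches to the genomic-left window. The
**gene body** is the unstranded TSS–TES span, introns included. A site
exactly at the TSS belongs to the gene body; since the promoter ends one
base 5′ of the TSS the two can never overlap, and gene body wins any
hypothetical tie. A site inside the promoter of one gene and the body of
an overlapping neighbour is assigned to both genes independently,
because the DMSG definition is per gene.

**Binding regions.** One representative (longest) transcript per gene is
used; the 5′UTR/CDS/3′UTR compartments tile the transcript, and a
binding site is labelled by maximal base overlap with ties broken
3′UTR > CDS > 5′UTR (the canonical priority of miRNA binding biology,
and a deterministic rule).

## Statistical choices

* **Pearson correlation** between per-time mean profiles (6 points
  including 0 h) with the t-transform p-value. Means per time are used
  because replicate counts differ across times; replicate-level pairing
  is not defined in this design. Correlations with r exactly 0 are
  labelled `zero` and excluded from positive/negative tallies.
* **Wilcoxon rank-sum**: exact null distribution when the pooled sample
  is ≤ 16 and tie-free — the regime of 3–6 replicates per group, where
  the normal approximation is poor — otherwise the normal approximation
  with tie and continuity correction. The bound is a visible parameter
  (`exactMax`).
* **Benjamini–Hochberg** for every multiple-testing correction.
* **Differential methylation** uses the pooled-count Fisher exact test
  rather than a replicate-aware overdispersion model; the cutoffs
  (25 points, q < 0.01, coverage 10) are the conventional site-level
  WGBS defaults and all configurable. Pooling discards
  between-replicate variance, which is why the simulator plants
  beta-binomial (not binomial) counts: the false-discovery behaviour of
  this stage is exercised against realistic overdispersed nulls in the
  test suite.
* **Built-in expression test** (for simulated data only):
  median-of-ratios size factors, log2 fold change of normalised group
  means with pseudocount 0.5, Welch t on log2(normalised + 0.5), BH.
  The pseudocount keeps zero counts finite and the Welch test avoids an
  equal-variance assumption; no claim of equivalence with
  shrinkage-based negative-binomial callers is made, and externally
  produced statistics tables are the intended production input.
* **Permutation p-values** use the add-one convention
  (1 + #{null ≥ obs}) / (iterations + 1), which cannot return 0 and is
  slightly conservative. Redrawing both sets each iteration is
  distributionally equivalent to fixing one; the null overlap is
  hypergeometric, and the suite checks the empirical null against the
  exact pmf (total-variation distance) and the empirical p against the
  exact tail.

## The simulator

`generateBundle()` emits, deterministically per seed, every input the
pipeline consumes plus truth tables. What it emulates:

* **Design**: the six sampling times with replicate counts 6/4/6/4/4/3;
  stage labels control/S1/R/S2.
* **Expression**: negative-binomial counts (dispersion 0.1) around
  log-normal baselines, with planted per-time log2FC profiles drawn from
  four shapes (sustained, early, late, stress-only) at mean effect
  |log2FC| = 2. Genes targeted by a differential miRNA inherit that
  miRNA's profile with the sign of the planted correlation, so
  anti-correlated pairs are recoverable from counts.
* **Targeting**: region weights default to (0.10, 0.70, 0.20) for
  5′UTR/CDS/3′UTR — CDS-dominated binding — with per-region negative
  correlation probabilities (0.70, 0.42, 0.73), i.e. UTR binding skews
  repressive while CDS binding is mixed. Both prediction files receive
  every true pair with energies in [−35, −20.5]; three decoy kinds
  (single-tool, weak-energy in one source, shuffled-gene) exercise every
  branch of the intersection filter and are never recoverable.
* **Methylation**: per-gene CpG counts Poisson with mean 3, multiplied
  by 0.85 in targeted genes (fewer methylation-capable sites); site
  baseline levels Beta-distributed around 0.20 with a 0.035 depression
  in miRNA-targeted genes — the scale of the published targeted versus
  non-targeted difference (about 0.19 vs 0.23), chosen as
  scale-matching, not as a fidelity claim; per-sample counts
  beta-binomial (concentration 50) at Poisson coverage 30. Sites in
  methylation-regulated genes shift by 30 points in all stressed
  samples, direction random but flipped when the shift would leave
  [0.02, 0.98].
* **Dual regulation**: the miRNA-regulated set is drawn uniformly; the
  overlap of the methylation-regulated set with it follows Fisher's
  noncentral hypergeometric distribution with the odds parameter solved
  numerically so that the *expected* overlap equals `rhoDual` times the
  independence expectation nA·nB/N. This makes `rhoDual` exactly what
  its name says — the enrichment factor of dual regulation over
  independence — with `rhoDual = 1` reducing to independent draws and
  `rhoDual = 0` forbidding overlap; configurations demanding an
  expected overlap at or beyond min(nA, nB) are rejected as infeasible.

What it does **not** emulate: nucleotide sequences and seed matching,
read-level noise, isoform structure (one transcript per gene, no
introns in generated models), non-CpG methylation contexts, batch
effects, and any coupling between methylation and expression beyond the
planted correlation signs. Passing tests therefore demonstrate that the
decision chain recovers planted effects of realistic size under
realistic replicate structure and overdispersion — not that any
particular biological dataset would yield the same numbers.

## Cohort and universe choices

Two genuinely open framing decisions are exposed as switches:

* **Classification cohort** (`cohort`): by default, modes are assigned
  to functional genes *differentially expressed* at the time point,
  since genes without an expression change have no regulated expression
  to explain; `cohort = "functional"` widens to all functional genes.
* **Permutation universe** (`universe`): by default the functional gene
  list, the analysis frame from which both regulated sets arise;
  `universe = "all"` uses every annotated gene, which makes the test
  more liberal.

## Problem sizes in the test suite

The suite favours many medium-sized simulations over few large ones:
recovery and calibration checks run 100–200 seeds at 60–700 genes,
the permutation null is validated at 10,000 iterations on universes of
16–30 genes where the exact law is computable, and oracle comparisons
use 1,000–10,000 random cases. These sizes give stable Monte-Carlo
margins (3 binomial/Monte-Carlo SDs wherever a rate is asserted) while
keeping the default run in minutes.

## Known limitations

* The pooled Fisher stage treats replicates as exchangeable libraries;
  strongly replicate-structured methylation variance will inflate its
  optimism relative to overdispersion-aware callers.
* Gene-level methylation is an unweighted site mean (a coverage-weighted
  mean is a one-line change but weights high-coverage sites, which is
  not obviously better); genes with no covered site are excluded from
  comparisons and counted.
* One representative transcript per gene; isoform-resolved binding-site
  assignment is out of scope.
* The correlation sign attached to a DMSG uses the pooled methylation
  profile of its single site; multi-site genes keep one record per
  site rather than a collapsed representative, and a "top site by
  |difference|" view can be derived from the per-site output.
* The enrichment hook for user-supplied term maps runs a plain
  one-sided hypergeometric test; no term databases ship with the
  package.
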