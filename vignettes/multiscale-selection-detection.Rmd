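---
title: "Detecting selection at SNP, gene and pathway scale: methods and design notes"
author: "adaptscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection at SNP, gene and pathway scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptscan)
```

# Overview

`adaptscan` implements a multiscale screen for the signature of natural
selection in a population resequencing panel of a nonmodel species —
typically a target-capture panel of a few hundred to a few thousand genes
genotyped in on the order of a dozen populations. Selection is interrogated
at three nested scales:

1. **SNP level** — rank correlation of population allele frequencies with
   climate variables across populations (a genotype–environment
   association, GEA), optionally combined with calls from external
   structure-aware GEA methods.
2. **Gene level** — a binomial outlier test asking whether a gene carries
   more climate-associated SNPs than expected from the panel-wide rate.
3. **Pathway level** — polygenic enrichment of per-gene sequence statistics
   (π, π~a~/π~s~, Tajima's D, Fu & Li's D\*/F\*) over curated gene sets,
   using the SUMSTAT score with overlap pruning and an empirical FDR.

The package also provides the underlying sequence statistics, the SNP
filter chain used to build a clean panel, climate pre-processing utilities,
and a seed-reproducible synthetic-data generator that makes the entire
pipeline testable without any external download.

# Data model

The central container, `GeaDataset`, extends `SummarizedExperiment`: the
`"geno"` assay is a SNP × sample matrix of **minor-allele copy counts**
(0/1/2, `NA` for missing), `rowData` carries per-SNP metadata (gene
assignment, position, coverage, heterozygote allele balance, site class)
and `colData$population` maps samples to populations. The minor allele is
defined over the full sample; a frequency tie at 0.5 is broken toward the
lexicographically smaller allele string so that re-loading a dataset is
reproducible. Per-gene sequence data live in `SiteAlignment` objects: the
2N unphased allele copies at every site (monomorphic sites included),
with fractional synonymous/nonsynonymous site weights.

Unphased diploids are handled throughout by working with allele copies:
every statistic used here (π, S, η, η~s~, allele frequencies) is a
function of per-site allele counts, so phase is never needed.

# SNP filtering

`filterSites()` retains polymorphic, biallelic SNPs with mean coverage in
a closed interval (default [20, 250]), heterozygote allele balance in
[0.3, 0.7], and missing-genotype fraction strictly below 0.15. A SNP
failing several rules is attributed to the first failing rule in a fixed
order (biallelic, polymorphic, missingness, coverage, allele balance) so
that filter reports are deterministic and their counts always reconcile
with the input size.

`hetExcessFilter()` screens for collapsed paralogs: at each SNP and
population the exact one-sided Hardy–Weinberg test for **heterozygote
excess** is applied, conditional on the observed allele counts
(enumerating heterozygote counts of matching parity under the Levene
distribution), and the SNP is removed when p ≤ 0.05 in at least four
populations. The test is exact, which matters at the typical 10 diploids
per population; populations with fewer than two genotyped individuals are
treated as untestable, never as significant. Both the per-population α and
the population threshold are exposed as parameters since different panels
warrant different stringency.

# Sequence statistics

For a site with $n_j \ge 2$ non-missing copies and allele counts $c_a$,

$$h_j = \frac{n_j}{n_j - 1}\left(1 - \sum_a (c_a/n_j)^2\right),$$

which equals the mean pairwise difference among the copies at that site.
Nucleotide diversity for a site class is $\sum_j h_j w_j / \sum_j w_j$
with the denominator running over **all** sites with $n_j \ge 2$,
monomorphic ones included — so values are per base pair and depend on the
accessible length, not only on the SNP panel. Sites with fewer than two
copies are excluded from numerator and denominator alike. Synonymous and
nonsynonymous site weights come from Nei–Gojobori fractional counting
(`classifyCodingSites()`): at each codon position the three possible
single-base changes are enumerated and the synonymous fraction becomes
$w_{syn}$; mutations to stop codons count as nonsynonymous.

Tajima's D contrasts the pairwise estimator of θ with Watterson's $S/a_1$;
Fu & Li's starred statistics contrast singleton mutations (alleles seen in
exactly one copy) with total mutations (D\*) or with pairwise diversity
(F\*). The starred coefficients use the corrected expressions adopted by
mainstream implementations — the originally published coefficient formulas
contain documented typographical errors. Because the classical formulas
assume a fixed sample size while real data have per-site missingness, the
per-gene n is taken as the **modal** per-site copy count by default
(`nMode = "max"` is available); the choice is reported alongside the
statistics.

Two properties back these implementations: π equals a brute-force
enumeration of pairwise per-site differences to 1e-12 on random alignments
with missing data, and on neutral coalescent simulations (n = 20, θ = 5)
the long-run means of D, D\* and F\* sit near −0.07, −0.07 and −0.08 —
slightly below zero, as expected for these statistics, whose numerators
have mean zero but whose random denominators co-vary with the numerator.
The same behaviour (mean D ≈ −0.074) is reproduced by an independent
coalescent simulator, so the small negative bias is a property of the
statistics, not of this implementation.

Inbreeding F is the method-of-moments observed/expected homozygosity
contrast per individual, and relatedness is the unadjusted A~jk~ moment
estimator computed from standardized genotypes; both are reported raw,
without clipping, and A~jk~ above ~0.6 between two samples flags probable
clones. Note that with sample-estimated allele frequencies A~jk~ between
unrelated individuals is centred slightly below zero (order −1/N).

# SNP–climate association and the gene-level outlier test

`spearmanScan()` computes, for every SNP × (climate variable, period)
pair, the Pearson correlation of mid-ranks (average ranks on ties) between
per-population minor-allele frequencies and the climate values, with a
two-sided p from the t approximation on m − 2 degrees of freedom. At the
target scale (m ≈ 12 populations) the t approximation is standard practice
and an exact permutation null is unnecessary; the scan's realized null
rejection rate at α = 0.01 is close to nominal (measured ≈ 0.01–0.02 on
null simulations, reflecting the approximation's mild liberality at small
m). Pairs with fewer than four populations of data, or zero variance, are
emitted as untested rather than silently dropped.

`geneOutlierTest()` then counts, per gene and climate column, the total
SNPs $n_i$ and the significant SNPs $a_i$, estimates the expected per-SNP
rate $P$ as the pooled proportion $\sum_i a_i / \sum_i n_i$ **over genes
with at least one significant SNP** (genes with zero are excluded from
the estimate but still reported), and flags genes with
$a_i > q_{0.9999}$, the smallest integer whose Binomial($n_i$, $P$) CDF
reaches 0.9999. Two readings of the published pooling formula exist; the
pooled proportion follows the cited procedure and the mean-of-ratios
alternative is available via `poolRule = "mean-ratio"`. The zero-exclusion
rule makes the test deliberately conservative: the excluded zero-count
genes inflate $P$, so the null flagging rate measured on simulations is
far below the nominal $10^{-4}$ per gene-column. It also means the test
only has power when genes carry many SNPs (the panel's genes average ~20
SNPs) and true signals involve several SNPs per gene.

`selectTopCandidates()` applies the final combination rule: a flagged
gene is retained only if at least two distinct SNPs in it are significant
for the **same climate variable** in the external association calls
(bayescenv Q < 0.05 and/or baypass BF > 30, pooled with OR semantics).
The published rule is explicit about matching the variable and silent
about the period; matching the period too is the default here
(`matchPeriod = FALSE` relaxes it).

# Pathway-level enrichment

The SUMSTAT score of a gene set is simply the sum of its members' values
for the chosen statistic. `sumstatTest()` compares it against the null
distribution of `nDraws` (default 100,000) uniformly drawn same-size gene
subsets, summarized by a fitted normal; p-values come from the fitted
normal rather than the raw empirical quantile so that p below 1/nDraws is
representable (the empirical mode is retained for cross-checks). The
sampling universe is every gene with a defined statistic and stays fixed
throughout pruning. On a 12-gene toy universe the fitted-normal p agrees
with exhaustive enumeration of all 495 subsets to about 0.01 on average;
individual sets can deviate by the discrete null's KS distance from the
normal (a few hundredths), which is immaterial at realistic universe
sizes.

`pruneAndTest()` removes redundancy between overlapping sets: test all
sets, emit the best (smallest tail p; ties broken by larger |z|, then set
id), delete its genes from all remaining sets, drop sets that fall below
the minimum size (default 5), and repeat. The procedure terminates in at
most as many rounds as there are sets, and every gene is removed at most
once. Because only each round's winner is emitted, the resulting p-values
are biased low and are **not** comparable to a nominal scale — hence
`empiricalFdr()`: the gene→statistic assignment is permuted over the
whole universe (preserving set sizes and the overlap structure), the full
prune-and-test pipeline is re-run per iteration (default 300), and

$$Q(p) = \frac{\operatorname{mean}_{iter} \#\{p' \le p\}}{\max(1, \#\{p_{obs} \le p\})},$$

monotonized to be non-decreasing in p and capped at 1. Permutation of
gene labels is the natural whole-pipeline null here; candidate pathways
are called at Q < 0.15. The null-sampling kernel draws subsets by a
partial Fisher–Yates shuffle in C++, driven by R's RNG so that every
result is bit-identical given a seed; it is statistically identical to
sequential random sampling but costs O(set size) rather than O(universe)
per draw.

# Climate utilities

`seasonalAggregate()` reduces monthly temperature/precipitation records
to seasonal means over fixed meteorological seasons
(December–February, March–May, June–August, September–November), taking
December from the same calendar year (the convention is recorded in the
output since sources differ). `gowerDistance()` is the calibrated climate
transfer distance — the unweighted mean of range-normalized absolute
differences between a source site's climate vector and a reference
(e.g. common-garden) vector; ranges should be computed over all source
sites plus the reference. `traitClimateCorrelation()` correlates
population trait means with climate, with an exclusion list for
sensitivity re-runs (e.g. dropping poorly replicated populations).

# The synthetic-data generator

`simulateCoalescentGene()` is a standard single-population Kingman
coalescent with infinite-sites mutation at rate θ/2 per lineage per unit
coalescent time, validated against Watterson's E[S] = θ·a~n~ and the θ/L
scaling of π. It deliberately omits recombination and demographic
history: it exists to calibrate the sequence statistics, not to model any
particular species.

`simulatePopulationPanel()` emulates the sampling design the pipeline
targets. Its defaults are fixed once and define the simulated study
conditions: 12 populations × 10 diploids; 1,100 genes with a Poisson(22)
number of SNPs each; eight bioclimatic variables (mean/seasonality/extreme
temperatures and annual/extreme/seasonality precipitation) in three
periods with across-period correlation 0.8; neutral population allele
frequencies from a Balding–Nichols beta draw with differentiation
parameter 0.1 (a realistic moderate F~ST~ for a fragmented tree species);
clinal genes whose SNPs follow logit⁻¹(a + βz) of one shared standardized
climate column with β = 2 and logit-scale noise SD 0.5; binomial genotype
sampling (2 copies per diploid) and 2% missingness. Clines are planted
**gene-coherently** — a clinal gene responds to one climate column through
about half of its SNPs — because the gene-level test is built around
multi-SNP signals, and independent per-SNP planting would misrepresent
the intra-gene correlation structure of real data. The external-call
simulator marks planted SNPs significant with sensitivity 0.8 and null
SNPs at a 1% false-positive rate; it stands in for the output format of
structure-aware GEA tools, not for their inference.

What the generator does **not** emulate: linkage disequilibrium between
SNPs beyond the shared cline, spatial autocorrelation of climate,
hierarchical population structure aligned with the environmental gradient
(the hardest confounder for GEA in real data), and sequencing artefacts
beyond simple coverage/allele-balance metadata. Passing tests therefore
demonstrate correctness and calibration of the statistics and procedures
under a clean, exchangeable null with planted monotone signals — not
robustness to structure–environment collinearity, which the external
structure-aware methods are meant to absorb.

# Numerical choices and degenerate inputs

* Undefined values are sentinels (`NA`), never silently zero: π~a~/π~s~
  with π~s~ = 0, neutrality tests with S = 0 or n < 4, relatedness for a
  pair with no shared usable site, correlations with zero variance.
* |ρ| = 1 maps to p = 0 in the rank scan (the t statistic diverges).
* A constant statistic universe makes the SUMSTAT null degenerate; both
  tail probabilities are reported as 0.5 with a `degenerate` flag.
* Pruning tie-breaks (p, then |z|, then set id) make emission order
  deterministic; all samplers run off R's RNG so a single seed fixes
  every result bit for bit.
* Problem sizes used by the packaged checks were chosen to finish a full
  run in minutes on one core: 1,000 coalescent replicates for neutrality
  calibration, 5,000 genes for the outlier-test null, 10,000 null draws ×
  100 FDR iterations × 50 replicates for pathway detection, and a
  500-gene × ~20-SNP panel for the end-to-end candidate-gene example.

# Known limitations

* Full replication of a real study's diversity table requires the
  original deposit (including invariant-site information to fix the
  accessible length L); the package reproduces the derived arithmetic and
  all statistic definitions, and `regionSummary()` accepts per-region L
  and per-class accessible totals when they are known.
* The Spearman p-value is approximate at small m and mildly liberal;
  with ~12 populations an exact-permutation option would change little
  at α = 0.01 but is not provided.
* The gene-level test inherits the conservatism of the zero-exclusion
  pooled rate; with small genes (few SNPs) it has essentially no power by
  construction.
* Fu & Li's D\*/F\* were validated against a re-derived implementation of
  the corrected coefficient formulas and against neutral-simulation
  calibration; no third-party starred-statistic implementation was
  available as an additional cross-check.
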