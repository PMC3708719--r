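---
title: "Rank-based comparison of trio GWAS across populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based comparison of trio GWAS across populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triorank)
```

## The problem

Genome-wide association results rarely replicate across ancestrally
diverse populations at a fixed significance threshold: allele
frequencies, effect sizes and linkage disequilibrium all differ, so the
same causal biology can surface at very different p-values. triorank
implements a threshold-free alternative for affected-offspring trio
studies: rank SNPs by association p-value within each population,
compare fixed-size top-n sets across populations at the SNP, gene and
pathway levels against explicit chance expectations, and relate
cross-population differences in association rank to population genetic
differentiation. The trio design matters here because the transmission
disequilibrium test (TDT) conditions on parental genotypes and is
therefore immune to population stratification — the pooled
"mega-analysis" across ancestries remains valid without any correction.

## Association model

At a biallelic SNP with alleles $M_1/M_2$, each parent transmits one
allele to the affected child. Let $b$ and $c$ count transmissions of
$M_1$ and $M_2$ from heterozygous parents (homozygous parents are
uninformative and land in the $a$ and $d$ cells of the transmitted
$\times$ non-transmitted table). Under the null of no linkage or
association the transmission probability from a heterozygote is
$\theta = 0.5$ and

$$\chi^2 = \frac{(b - c)^2}{b + c}$$

is asymptotically $\chi^2_1$. `count_transmissions()` resolves each
parent's transmitted allele by subtracting the other parent's forced
contribution from the child genotype; the only phase-ambiguous
configuration — both parents and the child heterozygous — contributes
one $b$ and one $c$ regardless of phase, so all counts are
phase-invariant. Trios with a missing member genotype or a Mendelian
inconsistency at a SNP are excluded at that SNP only, preserving their
information elsewhere; excluding the whole trio genome-wide would
discard data without any validity gain.

Quality control mirrors standard trio-GWAS practice: a SNP is kept when
its missing-call proportion over all individuals is below 0.15 and the
Hardy-Weinberg goodness-of-fit p on parental genotypes exceeds
$10^{-6}$. The HWE test is the asymptotic 1-df chi-square on founders
only: founders are the independent draws from the population, offspring
genotypes are induced by transmission and would bias the test. An exact
enumeration test (`hwe_test(..., method = "exact")`) is available for
small founder counts. The missingness denominator includes offspring as
well as parents, since a failed assay at any member removes the trio
from the transmission count.

The genomic inflation factor is
$\lambda = \mathrm{median}(\chi^2) / q_{0.5}(\chi^2_1)$ with
$q_{0.5}(\chi^2_1) \approx 0.4549$. Dividing every statistic by a
positive constant is strictly monotone, so genomic control can never
reorder SNPs — the entire rank-based pipeline is invariant to it. The
corrected p-values are available as an optional column but never drive
a ranking.

## Rank-based comparison

`rank_snps()` orders SNPs by p ascending with ties broken by
(chromosome, position); the tie-break is arbitrary but deterministic,
which is what reproducibility across platforms requires. Top-n sets for
n on a grid (default 1,000 to 50,000) are compared across populations
by exact intersection counts. The chance expectation treats each
population's top-n set as an independent uniform random subset of the
N SNPs passing QC in all compared populations:
$E[\text{pairwise}] = n_a n_b / N$ and
$E[\text{three-way}] = n_a n_b n_c / N^2$, by linearity of expectation
over SNPs. Replication of one population's top set in another is
counted at a nominal threshold (default $\alpha = 0.05$), with null
expectation $n\alpha$ — 5 for a top-100 set.

SNPs map to genes when they fall within the gene body or within 20 kb
of either end (most trait-associated variants lie within that
distance); the boundary is inclusive at exactly 20,000 bp. Coordinates
are handled internally in the 0-based half-open BED convention, with
1-based SNP positions converted on entry. The gene-level statistic is
the minimum p over mapped SNPs with the best SNP recorded; no
gene-size correction is applied at this stage, but the per-gene SNP
count is reported and the enrichment stage's resampling null absorbs
the bias.

## Pathway over-representation

A gene is *noteworthy* when its best SNP is in the top-n set
(equivalently, when any of its mapped SNPs is — the set is a prefix of
the same ranking). For each gene set the observed noteworthy-in-set
count is scored by the hypergeometric upper tail, and empirical
significance comes from resampling: each replicate draws a null
noteworthy list of the observed size and rescores every set, with

$$p_{\mathrm{emp}} = \frac{1 + \#\{r : C_r \ge C_{\mathrm{obs}}\}}{R + 1}.$$

Two null modes are provided because the literature is ambiguous about
what "gene resampling" should hold fixed. Mode `"gene"` samples genes
uniformly; mode `"snp"` (the default) samples SNPs and accumulates
their genes until the observed number of distinct noteworthy genes is
reached, so genes spanning many SNPs enter null lists proportionally
more often — exactly the gene-size bias of the observed construction.
When every gene has one SNP the two modes agree; with realistic gene
sizes only the SNP mode is calibrated, which is why it is the default.

The add-one form keeps $p_{\mathrm{emp}} \ge 1/(R+1)$ and makes the
p-value valid (never anti-conservative) for any $R$. The price is
discreteness: when expected in-set counts are small — a handful of
noteworthy genes falling in a modest set — ties between the observed
and null counts are common and $p_{\mathrm{emp}}$ is visibly
super-uniform (its mean exceeds 0.5). This is a property of every
resampling p-value, not of this implementation; our calibration test
therefore probes uniformity in a regime where in-set counts are large
enough (hundreds of scorable genes per set against a dense synthetic
annotation) for the discrete grid to be negligible, and separately
asserts the conservative floor in the sparse regime. A further caveat:
gene sets drawn from a common universe overlap, so their empirical
p-values are positively correlated and a Kolmogorov–Smirnov statistic
across sets fluctuates more than its nominal null allows; occasional
small KS p-values on perfectly calibrated output are expected.

## Population differentiation and discordant association

Per-SNP differentiation between two cohorts uses, by default, the
Nei-style $G_{ST}$ from allele frequencies:
$F_{ST} = (H_T - H_S)/H_T$ with $H_T = 2\bar p(1-\bar p)$ and $H_S$
the mean within-population heterozygosity — deterministic, bounded in
$[0,1]$, and zero exactly when the two frequencies coincide. The
Weir–Cockerham variance-components estimator is available when sample
sizes matter; it may be negative near zero differentiation.

For *parameter recovery* the two estimators differ sharply. Under the
Balding–Nichols model each population's frequency is
$\mathrm{Beta}\!\left(p\frac{1-F}{F}, (1-p)\frac{1-F}{F}\right)$ around
the ancestral $p$, with variance $F p (1-p)$. The per-SNP $G_{ST}$
between two such demes has expectation well below $F$ (the
ratio-of-expectations is $F/(2-F)$, and the mean per-SNP ratio sits
near $0.7F$ at $F = 0.05$), because $H_T$ measured from the pair of
demes absorbs part of the between-deme variance. The multi-locus
Weir–Cockerham ratio-of-sums (`fst_overall()`), by contrast, has
expectation exactly $F$ in the infinite-sample limit
($E[a] = Fpq$ against $E[a+b+c] = pq$ per locus), so it is the
estimator the package uses when recovering the simulation parameter;
the per-SNP $G_{ST}$ remains the default for the dependence analysis
below, where only the ranking of SNPs by differentiation matters.

Discordance in association between two populations is the absolute
difference in p-value ranks (DRP) after re-ranking within the shared
SNP set; the absolute value makes "large DRP" a two-sided measure of
disagreement. Both DRP and FST are dichotomized at their means
(strictly greater = high; ties fall low — arbitrary but documented),
and independence is tested with the 1-df Pearson chi-square on the
2x2 table, no continuity correction at genome-wide SNP counts (a
Yates flag exists). An observed high-high count above its expectation
with a small p says that strongly differentiated SNPs also tend to
rank differently for association — the signature expected when
ancestry-informative variation contributes to between-population
differences in disease risk.

## The synthetic-data generator

Every stage is exercised on simulated studies with known structure, so
the generator is first-class code, not a test fixture. It emulates:

* **Population structure** — ancestral MAFs uniform on [0.05, 0.5] by
  default, per-population frequencies from the Balding–Nichols Beta
  with a star phylogeny (each population independently displaced from
  the ancestor). Differentiation parameters near 0.01–0.15 span the
  within-continent to between-continent range.
* **Trios** — parents Hardy-Weinberg at the population frequency; each
  parent transmits one allele. Association is planted directly as
  transmission distortion: at risk SNPs a heterozygous parent
  transmits the risk allele with probability $\tau$ (0.5 = null,
  0.65 = a strong locus at 1,000 trios). This maps one-to-one onto the
  TDT's binomial parameter, so power is analytically checkable —
  at the cost of not modelling ascertainment through a liability
  scale.
* **Genome** — markers every 5 kb across 22 autosomes;
  non-overlapping genes with uniform lengths and enforced minimum
  gaps; gene sets of uniform random sizes, optionally with one set
  holding a planted fraction of the risk genes.
* **Data quality** — uniform independent missingness, optional
  Mendelian-error injection (default 0) to exercise the exclusion
  logic.

What it deliberately does not model: linkage disequilibrium (no stage
of the pipeline requires it; top sets in real data would contain
correlated SNPs, making effective set sizes smaller than nominal),
imputation, sex chromosomes, genotyping batch effects, and
ascertainment of affected offspring through disease liability. Passing
tests therefore demonstrate the statistical machinery is correct under
the stated model, not that real-data results are reproduced.

## Problem sizes and numerical choices

The shipped tests run scaled-down studies chosen to keep Monte-Carlo
error well inside the asserted tolerances: 10,000–20,000 SNPs,
200–1,000 trios per cohort, 300–2,000 genes, 100–500 gene sets,
200–1,000 resampling replicates, and 10 simulation replicates for
probabilistic claims (requiring 8 of 10 successes). Chance-overlap
checks use n = 1,000 from a universe of 100,000 with 10,000
Monte-Carlo draws. Tolerances follow the statistic at hand: 3 binomial
standard errors for rejection rates and transmission shares, 3
standard errors of the mean for Monte-carlo expectations, 20% relative
error for differentiation recovery at F = 0.05.

Degenerate inputs are defined rather than fatal: a SNP with no
heterozygous transmissions has an undefined (NA) statistic and is
excluded from rankings; a monomorphic SNP passes HWE trivially but is
flagged; an all-missing frequency yields an NA FST record that is
dropped with a logged count; a dichotomization with an empty margin
returns an NA dependence p with a warning. Stage seeds are derived
from the master seed by a stable string hash (`stage_seed()`), giving
independent, reproducible streams per stage and population.

## Limitations

Chance-expectation formulas for top-n overlap assume independent
uniform subsets; with LD or shared signal the observed counts are the
interesting quantity and the expectation is only a reference line. The
gene-level minimum-p statistic favours long genes — judge it together
with the reported SNP counts, or rely on the SNP-resampling empirical
p. The dependence test dichotomizes at means, which is simple and
matches the reporting convention it reproduces but discards
within-half variation; rank correlations would be a natural extension.
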