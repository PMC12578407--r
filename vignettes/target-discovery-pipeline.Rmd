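---
title: "Coexpression meta-analysis, planar network modules and key-driver discovery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coexpression meta-analysis, planar network modules and key-driver discovery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepnet)
```

# Overview

`hepnet` implements a network-based target-discovery pipeline for liver
disease transcriptomics. Starting from several independent patient cohorts
of log2 expression profiles, it:

1. tests gene-pair coexpression in each cohort with a permutation-based
   correlation test;
2. combines the per-cohort nominal p-values with Fisher's inverse
   chi-square statistic (ICS) and assesses it against an empirical
   resampling null, with Benjamini–Hochberg FDR across edges;
3. filters the significant edges to a planar maximally filtered graph
   (PMFG) and extracts coregulated gene modules at several resolution
   scales, reporting a scale-free topology fit per module;
4. ranks candidate regulators within each module by key driver analysis
   (KDA): enrichment of module members in a gene's n-layer network
   neighborhood, with n chosen to maximize the enrichment statistic;
5. annotates modules against gene-set collections by exact hypergeometric
   tests; and
6. classifies a perturbation or disease condition against a two-subset
   prognostic signature (poor-prognosis vs good-prognosis genes) with a
   weighted Kolmogorov–Smirnov GSEA engine, yielding a categorical
   poor / intermediate / good status.

Because genome-scale patient cohorts cannot be bundled or re-downloaded,
the package ships a synthetic multi-cohort generator with planted modules,
hub drivers and signature-responsive conditions. All statistical behavior
is validated on that generator against machine-readable ground truth.

# The statistical model, stage by stage

## Permutation correlation testing

For a gene pair $(x, y)$ with $n$ paired samples, the two-sided empirical
p-value for the Pearson correlation is

$$p = \frac{1 + \#\{\,|r_{\text{perm}}| \ge |r_{\text{obs}}|\,\}}{B + 1},$$

over $B$ random permutations of $y$. The add-one estimator never returns
zero, so logs of these p-values are always defined downstream. For vectors
of length $\le 8$ an exhaustive mode enumerates all $n!$ permutations and
returns the exact tail fraction; tests assert that the random estimator
converges to it.

Pearson correlation on log2 values is the default metric; a
signal-to-noise alternative exists for the GSEA ranking but the edge test
is deliberately simple. The test is two-sided because coexpression sign is
not restricted — negative coregulation is as informative for module
structure as positive. Pairs with fewer than three complete observations,
or constant on their complete observations, are dropped and logged rather
than guessed at.

Each pair receives its own permutation sub-stream, derived from the master
seed XOR a stable polynomial hash of the gene-id pair, so the p-value table
is independent of evaluation order and of which other genes are present
(this is asserted by a test).

## Fisher ICS meta-analysis with a resampling null

Per-cohort p-values $p_1, \dots, p_k$ for an edge are combined as
$\mathrm{ICS} = -2\sum_i \ln p_i$. Under independent uniform nulls this is
$\chi^2_{2k}$; permutation p-values are discrete and the planted signal
contaminates the marginal distribution, so significance is instead taken
from an empirical null: $10{,}000$ resampled ICS values, each formed from
$k$ p-values drawn with replacement from the pool of *all* observed
nominal p-values. The pool is global (shared across edges) rather than
per-edge; the null draws are therefore made once per meta-analysis, since
every edge with the same cohort count shares the same null distribution.
The empirical meta p-value uses the same add-one convention, and BH FDR is
applied across edges; edges with $q < 0.05$ enter the network, weighted by
their ICS.

Two numerical consequences are worth knowing. First, the meta p-value has
a floor of $1/(n_{\text{resample}}+1)$, so the number of resamples bounds
the attainable significance. Second, because the pool contains the
signal-bearing p-values, the null is conservative in signal-rich designs:
with only two cohorts and a high fraction of truly coexpressed pairs, the
attainable $q$ can stay above 0.05 no matter how many permutations are
run. Three or more cohorts (the design the pipeline targets) resolve this,
because the resampled ICS must draw $k$ small p-values at once.

## PMFG and multiscale modules

The planar filter is the classical PMFG greedy algorithm: candidate edges
are visited by weight descending (ties broken lexicographically on gene
ids, which makes the construction order-invariant — asserted by shuffling
input rows), and an edge is inserted iff the graph stays planar, stopping
at the planar bound of $3(|V|-2)$ edges. Every accept/reject decision is
recorded in a construction log.

Planarity is decided by Demoucron's face-embedding algorithm applied per
biconnected component, implemented in C++ for speed; no planarity test was
available in the installed graph libraries for R. The implementation is
validated against the classical certificates ($K_4$, $K_5$, $K_{3,3}$, the
Petersen graph, trees) and against an independent planarity implementation
on random graphs.

"Multiscale" module detection is realized as modularity (Louvain)
community detection on the PMFG at a sweep of resolution parameters
(default 0.5, 1, 2), with a fixed RNG seed and deterministic module
labelling (by size, then smallest member id). Communities smaller than
`min_size` (default 5) are discarded. The scale-free topology fit index —
the $R^2$ of the log–log regression of binned degree frequencies — is
reported per module as a diagnostic, not enforced as a hard gate: no
threshold is defensible a priori, and on planar subgraphs the degree range
is narrow, so the index is descriptive.

## Key driver analysis

For each candidate gene $g$ in a module $M$ within universe $U$ (all
network nodes by default), the $n$-layer neighborhood $N_n(g)$ (breadth-
first, excluding $g$) is scored by fold enrichment
$\frac{|N_n \cap M| / |N_n|}{|M| / |U|}$ and the exact hypergeometric
upper tail $P(X \ge |N_n \cap M|)$. The depth $n \in \{1, \dots, 5\}$
maximizing $-\log_{10} p$ is selected per gene (ties to the smaller $n$);
selected p-values are BH-adjusted within the module and genes ranked by
$(q, \text{fold descending}, \text{id})$. Depth 5 suffices because planar
module subgraphs have small diameters; the selected p is asserted to be
minimal over all searched depths. All module members are candidates by
default; a high-degree-only restriction is available as an option rather
than the default, since neither choice is canonical.

## Hypergeometric annotation

Module annotation is one exact hypergeometric test per (module, gene set)
pair — `stats::phyper`, no normal approximation — with one BH adjustment
across all pairs. A shuffled-module negative control (random "modules"
against random sets) is part of the acceptance checks and keeps the
fraction of $q < 0.05$ calls at or below the nominal level.

## GSEA engine and signature status

Genes shared by a test and a reference matrix are ranked by the difference
of group means on the log2 scale (descending); ties fall back to gene-id
order and the ranking is invariant under common per-sample shifts. The
running-sum statistic increments at set members by
$|s|^{w} / \sum_{\text{hits}} |s|^{w}$ (weight exponent $w = 1$ by
default; $w = 0$ recovers the classical KS statistic) and decrements at
non-members by $1/(N - N_{\text{hit}})$; the enrichment score (ES) is the
signed extreme of the running sum, which always starts and ends at zero
and lies in $[-1, 1]$. An all-zero ranking (e.g., test equal to reference)
carries no enrichment evidence and is defined to have ES 0.

Significance uses sample-label permutation when both groups have at least
three samples, otherwise gene-set permutation (the fallback is recorded on
the result). Following standard GSEA practice, the normalized enrichment
score divides the ES by the mean |ES| of same-signed null values, and the
empirical p-value is add-one against the same-signed side of the null:
$p = (1 + \#\{ES_{\text{null}} \ge ES\}) / (1 + \#\{ES_{\text{null}} \ge 0\})$
for positive ES. This convention makes the fully degenerate case
(identical matrices) return $p = 1$ exactly, with ties counted as
exceedances.

The signature-status call runs this machinery for the poor-prognosis and
good-prognosis subsets of a two-set signature and maps the pair of results
to a category: *poor* if the poor subset is induced or the good subset
suppressed at $q <$ `fdr_cut` while the converse pattern is absent; *good*
for the converse; *intermediate* otherwise. Conflicting double-significant
patterns resolve to *intermediate* and are flagged, rather than inventing
a dominance rule. The default cutoff is the customary GSEA exploration
threshold of 0.25; it is a liberal threshold by construction, so on pure
noise a minority of replicates will still receive a poor or good label —
the acceptance script reports this rate rather than hiding it.

# The synthetic generator: what it emulates and what it does not

Each cohort draws, per module, a latent factor $f \sim N(0,1)$ over
samples. The module's driver gene is $f$ plus small noise
($\mathrm{sd} = 0.1 \cdot \sigma$), and each member is
$\beta \cdot \text{driver} + \varepsilon$ with
$\mathrm{sd}(\varepsilon) = \sigma \, \beta \sqrt{(1-\rho)/\rho}$. This
calibration makes the expected within-module correlation $\approx \rho$ at
the reference noise level $\sigma = 1$ and drives correlations to 1 as
$\sigma \to 0$. The latent-factor construction (rather than sampling a
block covariance directly) gives the driver a *topological* identity — it
is the hub through which module signal flows — which is exactly what key
driver analysis needs as ground truth. Background genes are independent
noise; every gene gets a baseline shared across cohorts and a per-cohort
additive batch shift (no multiplicative batch effects — the simplest
structure that still stresses the meta-analysis). Signature responses are
planted additively: $+\delta$ on poor-prognosis genes, $-\delta$ on
good-prognosis genes, in injured samples only, so a knockout-style
reversal is simply a second planting with $-\delta$.

Defaults were chosen once as the study conditions: 3 cohorts of 50
samples; modules of 10, 15 and 20 genes at $\rho = 0.6$; driver loading
$\beta = 0.9$; 60 background genes; noise sd 1; batch shift sd 0.3;
signature effect $\delta = 2$ in log2 units with a 73-gene poor and
113-gene good subset. Cohort count and the signature subset sizes mirror
the multi-cohort liver-disease designs this pipeline is meant for; the
correlation and loading values are calibration choices in the range of
well-formed coexpression modules, not estimates from any particular
dataset.

The generator deliberately does **not** model: count-based RNA-seq noise
(values are continuous log2 intensities), gene-length or library-size
effects, correlated background structure, overlapping modules,
multiplicative batch effects, or missingness patterns. Passing the
recovery checks therefore demonstrates that the statistical machinery is
correct and well calibrated under its stated model — not that it is robust
to every artifact of real cohort data.

Determinism: one global RNG (R's Mersenne–Twister) is seeded per spec;
per-cohort sub-streams use fixed seed offsets, so adding a cohort never
perturbs earlier cohorts, and identical spec + seed reproduces
byte-identical matrices on any platform.

# Numerical choices and degenerate inputs

* Add-one estimators everywhere a permutation or resampling p-value is
  formed; ties count as exceedances (with a $10^{-12}$ absolute tolerance
  on floating-point comparisons).
* Constant vectors are an explicit error in the pairwise test; within the
  all-pairs table they drop the pair with a log entry instead.
* Housekeeping z-scoring treats a row as constant when its post-centering
  sd falls below $10^{-12}$; such rows become all-zero with a warning, not
  an error.
* PMFG tie-breaks are lexicographic on (gene_a, gene_b); module ids are
  deterministic given the seed; KDA depth ties go to the smaller depth.
* The candidate shortlist treats annotation flags as tri-state: unknown
  fails a required flag but is reported separately from false, and genes
  with no annotation row are surfaced in an "unannotated" section rather
  than dropped.

# Problem sizes used in the shipped checks

The test-suite and the acceptance script exercise the pipeline at desk
scale, chosen so the full statistical battery (oracle equivalence, null
calibration with 2,000 null pairs and a 10,000-draw resampling null,
20-seed recovery of the default study, 40-replicate signature calls, and
double end-to-end runs) completes in a few minutes: 105-gene universes
for the recovery studies and 300-gene universes for the signature studies.
Every number the documentation quotes is produced by those scripts at run
time.

# Known limitations

* The planarity-filtered module stage is the classical PMFG plus
  resolution-swept Louvain; the multiscale decomposition used by the
  original planar filtered network analysis literature is not publicly
  specified, so this package documents its stand-in rather than claiming
  equivalence.
* The resampling null is conservative when the p-value pool is
  signal-rich, noticeably so for two-cohort designs (see above).
* KDA is purely topological on an undirected graph; no causal or directed
  claims are made about "drivers".
* The GSEA ranking metric is a group-mean difference; for very small
  groups the gene-set permutation fallback gives less sharp nulls.
* Scale-free fit is reported, never enforced; on small planar subgraphs
  its discriminative power is limited.
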