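---
title: "Methods: meta-analysis, risk scoring, multiplicative risk simulation and network prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis, risk scoring, multiplicative risk simulation and network prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rasysgen)
```

`rasysgen` implements a systems-genetics workflow for a complex disease,
developed around rheumatoid arthritis (RA): validate candidate risk
variants by re-analysing published meta-analyses, weigh them into a
genetic risk score and measure its discrimination, ask by simulation how
many as-yet-undiscovered loci would be needed for clinically useful
prediction, and prioritise candidate genes by network proximity to the
known risk genes. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Meta-analysis re-analysis

Per-study effects are per-allele log odds ratios. From an allele-level
2×2 table they are `log(ad/bc)` with standard error
`sqrt(1/a + 1/b + 1/c + 1/d)`; when any cell is zero, 0.5 is added to
all four cells (Haldane–Anscombe — the source analyses do not state a
correction, and this is the standard one). When a study is available
only as `OR (95% CI)`, the standard error is recovered as
`(log U - log L) / (2 * 1.96)`.

Pooling is inverse-variance fixed-effects and DerSimonian–Laird
random-effects, with the method-of-moments between-study variance
`tau2 = max(0, (Q - df) / C)`, `C = sum(w) - sum(w^2)/sum(w)`. When
Cochran's Q does not exceed its degrees of freedom, `tau2` truncates to
zero and the two models coincide — a property the tests assert.
Heterogeneity is quantified by `I2 = max(0, (Q - df)/Q) * 100`, with
values above 50% flagged as large, and the Q test is read at the 0.1
level. All pooling p-values are two-sided normal.

Two analyses around the pooling needed a modelling decision because the
original report states only the result:

* *Excess heterogeneity.* Whether significant Q tests are more frequent
  than chance expects is tested as the upper binomial tail
  `P(X >= n_significant)`, `X ~ Binomial(n_tests, 0.1)` — the Q-test
  level itself. With 10 significant tests out of 20 this reproduces the
  reported order of magnitude (`7.2e-6`) exactly to two significant
  figures, which is why the binomial reading was adopted.
* *Ethnic-subgroup heterogeneity.* Differences between, say, East Asian
  and European pooled effects are tested by a two-sample z-test on the
  fixed-effects pooled log-ORs.

Variant selection keeps variants passing the association gate
(meta-analysis `P < 2.5e-3`, i.e. 0.05/20, or genome-wide `P < 5e-8`)
with minor allele frequency of at least 5% in the target population.
An ethnicity-specific OR replaces the overall one only when the
subgroup analysis has ≥3 studies and ≥2,000 subjects in both groups,
a significant target-group effect, and significant between-group
heterogeneity at 0.05. The 2,000 threshold is read as subjects, not
alleles (the more common convention for "cases and controls").

## Genetic risk score and its discrimination

The score of a subject is

    S = sum_i x_i log OR_i  +  sum_j I_j log OR_j

over SNP dosages `x_i` in {0,1,2} and HLA-DRB1 allele indicator counts
`I_j` (at most two HLA terms per subject). Three models are exposed:
HLA-only, non-HLA-only, and the integrative model that uses both; by
construction the integrative score is the sum of the other two. Weights
default to fixed published/pooled log-ORs; a refitted logistic linear
predictor is available through `fit_logistic()` and gives the same AUC
whenever the two are monotonically related. Subjects missing any model
genotype are excluded (complete-case; the original cohort retained
1,231/1,445 of 1,287/1,500 this way), and SNPs failing the
Hardy–Weinberg exact test in controls at `P < 0.001` are excluded
upstream — both mirrored here as policy, not heuristics.

AUC is the Mann–Whitney estimator (ties count one half), its confidence
interval and the paired comparison of two models use the DeLong
placement variance — the original report gives CIs and a p-value
without naming the method, and DeLong is the field default. Score
distributions are compared by a two-sided Mann–Whitney test (again
unnamed in the source; a permutation alternative is provided and agrees
within Monte-Carlo error in the tests). Score densities use a Gaussian
kernel with Silverman's rule by default; HLA-driven scores are
multimodal because the few strong HLA genotype classes separate in
score, and the tests check that the density machinery resolves this.

## The constrained multiplicative risk model

The simulation engine represents disease risk of a multilocus genotype
X as

    f(X) = min(1, b * prod_l OR_l^{X_l}),    P(X) = prod_l P(X_l)

with every locus in HWE and linkage equilibrium. The background `b` is
calibrated so the population mean risk equals the prevalence `K`
(default 0.01, the RA figure). Two calibrations are offered because the
literal model is ambiguous about the cap:

* `uncapped` (default): `b = K / E[prod OR^X]` in closed form, the cap
  applied afterwards. The realised prevalence then falls short of `K`
  by the capped mass, which the result reports.
* `exact`: bisection on `b` so that `E[min(1, b prod)] = K` to 1e-10.

Status-conditional genotype distributions follow by Bayes inversion,
`P(X|case) ∝ f(X) P(X)` and `P(X|control) ∝ (1 - f(X)) P(X)`, and the
ROC sweeps every distinct risk value as a cut-off; the trapezoid AUC
equals the pairwise probability that a case's risk exceeds a
control's, ties counting one half (asserted against exhaustive
enumeration for small scenarios).

Numerically, the engine convolves per-locus log-multiplier
distributions sequentially. Blocks of N identical hypothetical loci
collapse to a Binomial(2N, p) risk-allele count, which makes the
"N additional loci" sweeps cheap. Support values equal within relative
tolerance 1e-9 are merged; when the support exceeds the budget
(`max_support`, default 16,384 points) it is compressed onto a
probability-weighted grid, which perturbs the AUC by far less than the
0.1-point level at the default budget (the tests compare compressed
against uncompressed runs). With compression disabled the engine
errors instead, and a seeded Monte-Carlo path (`monte_carlo_auc()`,
exact status-conditional sampling with rejection for the cap) serves
as an independent cross-check. Zero-probability states from
underflowed binomial tails are dropped before merging.

`loci_needed()` finds the smallest N of additional loci (given OR and
risk-allele frequency) reaching a target AUC by doubling then
bisection, which is valid because AUC is non-decreasing in N; the
tests verify the result against a plain linear scan. The companion
`naive_auc_single_point()` converts a published sensitivity/specificity
operating point into the AUC of the two-segment ROC through it,
`(sens + spec)/2` — the anti-CCP point (67%, 95%) gives 81%. The
analogous arithmetic for IgM RF (69%, 85%) gives 77%, not the 75%
printed in the source; the discrepancy is noted here and not asserted.

### The bundled base-variant table is a synthetic stand-in

The published base-model simulation is conditional on Japanese allele
frequencies from the study's supplementary material, which is not
redistributable and not reproduced in the main text. The file
`inst/extdata/synthetic_base_variants.tsv` therefore carries the
published univariate odds ratios together with *synthetic* allele
frequencies — plausible Japanese-population values chosen once when
the file was written and not revisited. On this stand-in the identical
computation gives a base-model AUC near 66.1% rather than the
published 71.0%, and correspondingly larger additional-locus counts,
while the HLA-dominated combination scenarios land within one to two
AUC points of the published 80.2%/95.2%. The acceptance-style test
asserting the published numbers is expected to fail on the stand-in
and is kept failing deliberately: it documents exactly which results
require the original frequency table. Users with access to the real
frequencies can drop them into the same file format and rerun.

A related reading decision: the univariate OR column is the default
base-model input (matching the stated source of the ORs), although the
original report itself notes that univariate HLA ORs are attenuated
because the referent group pools the other risk alleles; the
multivariate column can be supplied in the same table format.

## Network prioritization

The protein–protein interaction network is an undirected simple graph;
loading upper-cases symbols, collapses duplicate edges, removes
self-loops and drops isolated vertices (a walk is undefined there).
Both plain two-column edge lists and the HPRD flat-file layout
(symbols in columns 1 and 4) are read. Variants map to single genes by
the context hierarchy coding > intronic > 5'UTR > 3'UTR > near gene
(2 kb 5' / 0.5 kb 3'), with curated overrides for intergenic variants.

The random walk with restart iterates
`p(t+1) = (1-r) M' p(t) + r p(0)` with the degree-normalised
transition matrix `M[v,w] = A[v,w]/k_v`, restart probability `r = 0.5`
and uniform seed distribution, until the L1 change is at most 1e-10.
The iterate is checked against the direct linear solve
`p = r (I - (1-r)M')^{-1} p(0)` on graphs up to 500 vertices, and
probability mass is conserved throughout. Non-seed genes are ranked by
steady-state probability, ties broken deterministically by symbol and
annotated; seeds are excluded from the candidate ranking (the original
analysis reports its top candidate among non-seeds), configurably.

Leave-one-out cross-validation withholds each seed in turn and records
its rank among itself plus all non-seed genes (both denominators
offered, since the source is ambiguous by one). The ROC over a sliding
rank threshold and its trapezoid AUC quantify recovery; planted-module
synthetic networks give AUC > 0.9 against ≈0.5 for unwired seeds, and
rankings are stable in `r` (Spearman > 0.9 across 0.3/0.5/0.7 on
planted networks — a property check, since the published correlation
range was measured on a specific external database version).

## Overlapping modules and enrichment

The disease subnetwork (seeds plus the top-100 ranked genes, `top_k`
configurable; 50/100/150 nest) is clustered with EAGLE: initial
communities are maximal cliques of at least `clique_min = 4` vertices
(the value used by the algorithm's authors for PPI networks; the
source does not state it) plus singletons for uncovered vertices;
communities are merged greedily by the modularity-style similarity,
ties broken by the lexicographically smallest pair so the dendrogram
is deterministic; and the cut maximising the extended modularity EQ —
modularity weighted by `1/(O_v O_w)` for vertices in `O_v`
communities — is selected. On small graphs the selected cover attains
the exhaustively enumerated best partition EQ, and covers of disjoint
cliques reproduce hand-computed values. Communities with more than 10
vertices correspond to the reported "complexes".

Enrichment replaces a web-service annotation step with a local
one-sided hypergeometric test of each GMT gene set against a fixed
background (the network's gene universe), reporting overlap count,
percentage of the cluster, fold enrichment, raw and
Benjamini–Hochberg-adjusted p-values; an EASE-style overlap−1 variant
approximates DAVID's conservative score. Exact published enrichment
values are out of scope — they depend on a dated annotation snapshot.

## Synthetic-data generators

The generators exist so every pipeline stage is testable without
external or private data, at the study's scale by default but
config-driven for fast runs:

* `gen_cohort()` samples case/control genotypes *exactly* under the
  constrained multiplicative model: cases from per-locus tilted
  distributions (∝ frequency × multiplier, exact for the uncapped
  product) with rejection correcting for the cap, controls from the
  population distribution accepted with probability `1 - f(X)`. No
  rare-disease approximation is made, so the exact engine's AUC is the
  true value for the sampled cohorts — the pipeline's central
  consistency property, asserted end-to-end at 4,000/4,000 subjects
  within three standard errors. Missingness is uniform at random
  (default 1%, matching the reported at-most-1.3%).
* `gen_meta_studies()` draws per-study true log-ORs from
  `Normal(theta, tau2)` and binomial allele counts; DL pooling
  recovers both parameters across replicates, and null studies give a
  calibrated fixed-effects type-I error.
* `gen_ppi()` grows a scale-free background (preferential attachment
  default, a duplication–divergence variant provided) and wires a
  planted seed set at a chosen density — the proximity signal LOOCV
  should detect.
* `gen_gene_sets()` emits GMT terms, optionally oversampling a target
  cluster so enrichment has a planted positive.

What they do **not** emulate — and hence what green tests do not show
about real data: linkage disequilibrium between loci (the model
assumes linkage equilibrium), population stratification, genotyping
error beyond uniform missingness, the degree correlations and
ascertainment biases of curated interactomes, and the semantic
structure of real annotation databases.

All generators are pure functions of configuration plus a mandatory
integer seed; replays are byte-identical.

## Problem sizes and runtime choices

The shipped test-suite sizes are the package's own choices for a
single-CPU desk run: oracle comparisons up to 200 subjects per group,
6 loci, 500-vertex walks and 8-vertex exhaustive cover enumeration;
1,000 seeded replicates for the 95% coverage check (400/400 subjects
each); 200 replicates for meta-analysis recovery; 20,000 draws for the
Monte-Carlo/exact cross-check; and a 16,384-point support budget for
the convolution engine. The full suite runs in a few minutes.

## Known limitations

Beyond the generator caveats above: the base-variant file's allele
frequencies are synthetic stand-ins (see the simulation section), the
cohort-specific published estimates (per-variant ORs, the 68.4%/70.9%
AUCs) are not reproducible because the genotype data are private, and
database-version-dependent network counts are logged rather than
asserted. The between-subgroup z-test and the binomial
excess-heterogeneity model are inferences about unnamed methods,
flagged as such above.
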