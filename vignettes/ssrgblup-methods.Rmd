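---
title: "Methods: single-step genomic evaluation with SSR allele markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-step genomic evaluation with SSR allele markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrgblup)
```

## The problem this package addresses

Perennial forage trials measure the same clonal genotypes repeatedly
over harvest cycles ("cuttings").  When only a multiallelic SSR
(microsatellite) panel is available — and some individuals were never
genotyped at all — genetic evaluation has to combine three things:

1. a marker coding that turns multiallelic, possibly polyploid SSR
   calls into usable covariates,
2. a relationship structure that covers genotyped *and* ungenotyped
   individuals in one analysis (single-step GBLUP), and
3. a repeated-measures mixed model that separates genetic effects from
   genotype-by-cutting interaction, block and permanent-environment
   effects.

On top of the evaluation model the package runs a per-cutting
single-marker association scan with FDR control and pairwise linkage
disequilibrium (r²) profiling, and it ships a simulator that generates
study-shaped data sets with known ground truth so every stage is
testable without any external data.

## Marker coding, quality control and imputation

Each distinct allele observed at an SSR locus becomes one binary
marker: entry 1 when the genotype's call set at that locus contains the
allele, 0 when the locus was called without it, and missing when the
whole locus call is missing (a genotype cannot be "present-unknown"
for one allele yet observed for another at the same locus).  Column
order is locus order as read, then ascending allele size, so marker
indices are reproducible.

Quality control drops markers with call rate below 0.85 and markers
with minor-allele frequency below 0.01 (both configurable).  The MAF
rule is applied in the standard direction — *low*-frequency markers are
removed.  Imputation then replaces each missing entry in column *i* by
0 when the presence frequency over observed entries satisfies
`p_i <= 0.5` and by 1 otherwise; the boundary `p_i = 0.5` goes to the
0 branch by the rule's definition.  Frequencies used for imputation are
computed from the observed entries of the post-QC matrix (QC first,
then imputation); the frequencies stored on the completed matrix are
recomputed from it so the centered matrix `Z* = Z - P` has exactly zero
column sums.

## Relationships

The genomic relationship matrix is

&nbsp;&nbsp;`G = Z* Z*' / sum_i p_i (1 - p_i)`

which for binary presence/absence markers gives `trace(G) = n` and zero
row sums whenever `p` is computed from `Z` itself.  The zero row sums
mean G is always singular, so before inversion it is blended with the
pedigree submatrix, `G* = 0.95 G + 0.05 A22` (weight configurable);
with `A22 = I` the smallest eigenvalue of `G*` is at least 0.05.  No
other jitter is applied anywhere — blending is the sanctioned
regularizer.

With ungenotyped individuals present, the single-step precision matrix

&nbsp;&nbsp;`H^-1 = A^-1 + [0 0; 0 G*^-1 - A22^-1]`

covers everyone; with no pedigree information `A = A22 = I`, so the
ungenotyped block of `H^-1` is the identity and the genotyped block is
`G*^-1`.  Individuals are ordered ungenotyped-first and that ordering
is honored by every downstream incidence matrix.

## The mixed models

The full evaluation model for the multi-harvest data is

&nbsp;&nbsp;`y = Xm + Za + Zg + Wb + Ti + Tr + Qp + e`

with fixed cutting-by-replication means `m` and random terms: additive
genetic `a ~ N(0, H sigma2_a)`, residual genetic `g ~ N(0, I sigma2_g)`
(non-additive variation not captured by the markers), block
`b ~ N(0, I sigma2_b)`, genotype-by-cutting interaction
`i ~ N(0, G_i sigma2_i)`, residual interaction `r ~ N(0, I sigma2_r)`,
permanent environment `p ~ N(0, I sigma2_p)` and residual `e`.  The
no-relationship benchmark (simple repeatability plus interaction model)
drops `a` and `r` and keeps a single independent genotype term.

Design choices the model statement leaves open:

* **Interaction covariance `G_i`.**  Implemented as block-diagonal over
  cuttings with the genotype relationship inside each block
  (`kron(I_cuttings, H)`): interaction effects are correlated across
  genotypes through the relationship but independent across cuttings.
  A switch selects a plain identity instead.
* **Permanent environment.**  Mapped to the plot (genotype x
  replication) unit.  A genotype-level identity term would be fully
  confounded with `g`; the plot-level term is the standard
  perennial-trial usage.
* **Blocks.**  When the phenotype table has no Block column the term is
  dropped with a warning rather than silently absorbed.
* **Fixed effects.**  Reference-level (full-rank) coding, first level
  of the factor as reference.

## REML estimation

Variance components are estimated by restricted maximum likelihood on
Henderson's mixed-model equations.  The baseline algorithm is EM-REML
(monotone in the restricted likelihood, assertable per iteration); the
`"ai"` option runs a short EM warm-up and then average-information
updates with step-halving, falling back to an EM step whenever the AI
step leaves the parameter space or decreases the likelihood.  The
restricted log-likelihood is evaluated from the factored coefficient
matrix via `log|V| + log|X'V^-1 X| = log|R| + log|D| + log|C|`, which
the test suite cross-checks against a direct dense-V computation.

Numerical choices:

* Convergence: maximum relative component change below `tol`
  (default 1e-8), iteration cap 500, non-convergence is an error that
  carries the iteration trajectory.  A secondary rule declares
  convergence when the restricted log-likelihood is stationary
  (relative change below `ll_tol`, default 1e-10) for three consecutive
  iterations — this is reached on flat likelihood ridges, e.g. when two
  random terms are aliased and only their sum is identified.
* Boundary: components are floored at `1e-8 * var(y)`; a component held
  at the floor for five consecutive iterations is pinned there and
  reported as zero.
* Prediction error variances (PEV) are the diagonal of the inverse
  coefficient matrix; per-level accuracy is `sqrt(1 - PEV/sigma2)`,
  clamped to [0, 1], and the per-trait summary is the mean over
  genotype levels (median available).
* Likelihood-ratio tests for one random term use `2 * delta logL`
  against the chi-square with 1 df at the 5% level (critical value
  3.84).  At the zero boundary this reference is conservative (the
  asymptotic null is a 50:50 mixture of chi-square 0 and 1); the
  simpler chi-square(1) convention is kept deliberately and the
  conservative direction is covered by a type-I-error simulation.

## Association scan and FDR

Per cutting, the scan model is `y = Xm + Mu + Za + Zg + Wb + e` with
the marker as a single fixed covariate.  Components are estimated once
under the no-marker null and every marker is then tested by generalized
least squares at those components (the standard two-step mixed-model
scan); a flag enables full per-marker re-estimation for cross-checks.
Wald statistics `(u/se)^2` are referred to chi-square(1).  Because the
per-cutting subset contains genotyped individuals only, the genotype
covariance is the blended `G*` — the raw `G` from a modest marker panel
is rank-deficient and the blend is the same regularizer used on the
relationship side.

The FDR rule is Benjamini–Hochberg step-up at rate `q = 0.02`
restricted to the screened set `p < 0.05`: the threshold is `-log10` of
the largest order statistic `p_(k) <= k q / m` that also passes the
screen, and markers at or above the threshold are declared.  Both knobs
are exposed.  Markers constant within the analyzed subset are reported
with missing p-values, not dropped silently.

## Linkage disequilibrium

For binary presence profiles the classical haplotype-frequency r² —
`[p(AB) - p(A)p(B)]^2 / (p(A)p(B)(1-p(A))(1-p(B)))` — is computed by
treating each genotype's 0/1 pair as one two-locus observation.  With
unphased presence/absence SSR data this is the only computable reading,
and on 0/1 vectors it equals the squared Pearson correlation, which the
tests use as an independent oracle.  LD is computed on the post-QC,
post-imputation matrix, matching the association-scan input.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults state the world the package is designed for:
100 clonal genotypes of which 90 genotyped, 18 SSR loci with 4–8
alleles each (about 110 expanded binary markers), 5 cuttings x 2
replications with 10 incomplete blocks of 10 plots per replication, and
phenotypes drawn from the full evaluation model.  Default true
components `(a, g, b, i, r, p, residual) = (1, 0.5, 0.25, 0.5, 0.25,
0.25, 1)` give an individual-record heritability near 0.3 with
interaction variance half the additive variance — a realistic profile
for perennial-forage traits — and the fixed cutting-replication means
are drawn once around a grand mean of 10 with spread 2.

Implementation notes: allele frequencies per locus are flat-Dirichlet;
a genotype's call is four draws with replacement (a tetraploid-like
dosage collapsed to presence), so every called locus carries at least
one allele.  True additive values are drawn jointly over genotyped and
ungenotyped individuals from the H matrix (identity coupling for the
ungenotyped), so prediction of ungenotyped individuals genuinely
exercises the single-step machinery.  Blocks are random intercepts
nested in cutting x replication with a physical plot layout fixed
across cuttings.  One master seed drives named RNG streams per stage,
so runs are byte-identical and stages can be regenerated independently.

What a green test on simulated data does **not** establish: the
generator draws markers in linkage equilibrium (no population
structure, no real LD between loci), phenotypes are exactly Gaussian
with homogeneous residual variance across cuttings, and the lattice is
simulated as plain nested blocks without alpha-design optimization.
Agreement with published values from a real trial is checked separately
and only when the original supplementary tables are supplied (see the
acceptance tests); those files could not be bundled, so the
corresponding checks fail with an explicit message in a data-less
checkout.

## Scaling of the simulation-based tests

The parameter-recovery and type-I-error batteries run at a reduced but
structurally identical scale (about 25–30 genotypes, 2–3 cuttings)
because 100+ full-scale REML fits would take hours on one CPU; the
full study-scale single fit is exercised once in the suite.  The
boundary-conservativeness argument for the LRT and the unbiasedness of
REML are scale-free, which is what those tests assert.

## Known limitations

* Single-trait models only; no heterogeneous residual variances per
  cutting, no spatial row-column adjustment, no Bayesian machinery.
* The association scan offers no population-structure covariates by
  design (the intended setting is a single-cluster germplasm
  collection).
* Dense linear algebra throughout: comfortable to a few thousand
  mixed-model equations, not intended for SNP-scale panels.
* LD is reported without positions (SSR panels here have none), so no
  decay-versus-distance analysis.
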