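---
title: "Models and methods behind the sciurognath pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the sciurognath pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sciurognath)
```

## What the pipeline estimates

The package analyses endocast measurements of extant and fossil
sciuromorph rodents (squirrels, the mountain beaver and their extinct
ischyromyid relatives) to ask how locomotor behaviour relates to brain
size and to the size of three brain regions — the neocortex, the
petrosal lobules and the olfactory bulbs — once body size and shared
ancestry are taken into account. The workflow is: stochastic
time-calibration of a fixed topology from fossil age bins; PGLS
allometry and a phylogenetic encephalization quotient; permutation
tests across five locomotor categories; six PGLS regressions with
covariance-model selection; non-phylogenetic RRPP ANOVA with post-hoc
tests; and ancestral reconstruction of both continuous traits and the
discrete locomotor character.

## Time-calibration

The topology is treated as known; only node ages are uncertain. Each
fossil tip age is drawn uniformly within its first-appearance interval
(the bins of the North American Land Mammal Ages have a typical width
of 2–5 Myr), and node ages are then assigned in post-order as

> age(node) = max(age(children)) + mbl + Exp(mean = 2 Myr),

with a minimum branch length `mbl = 0.1` Myr. This is a deliberate
simplification of calibration methods that model branching, extinction
and sampling rates explicitly: those rates are not identifiable from
the inputs this pipeline consumes, and every downstream stage uses
only a dated tree. One hundred calibrations are drawn (per-tree seeds
are `master_seed * 1000 + i`, so any tree can be regenerated in
isolation) and summarized by the per-node arithmetic mean of ages on
the shared topology — on a fixed topology all among-tree variation is
in the node ages, so the mean-age tree is the natural consensus.
Extant tips sit at age 0; the shared Pleistocene first-appearance bin
(2.58–0.0117 Ma) is carried in the age matrix only as a feasibility
bound. Tree-dependent results inherit the calibration's stochasticity;
they are reported per seed and should be read with that in mind.

## Covariance models and PGLS

Under Brownian motion the covariance of a trait between two species is
proportional to their shared path length `C[i,j]` (MRCA height above
the root). The four selectable structures are:

* **brownian** — `V = C`;
* **lambda** — off-diagonals of `C` multiplied by Pagel's λ ∈ [0, 1],
  diagonal unchanged (λ = 1 is Brownian, λ = 0 a star phylogeny);
* **early_burst** — each edge spanning root-height interval [t0, t1]
  rescaled to `(exp(r t1) − exp(r t0))/r` with r ≤ 0, so evolutionary
  rate decays from the root (r = 0 recovers Brownian motion);
* **ou** — the stationary Ornstein–Uhlenbeck correlation
  `exp(−α d[i,j])` with unit diagonal, where `d` is patristic
  distance. On a non-ultrametric, fossil-bearing tree several OU
  parameterizations exist and genuinely differ; the stationary form is
  used because it is well defined there and matches the
  Martins–Hansen correlation structure of the standard GLS tooling
  (our OU fits agree with that structure's ML estimates to machine
  precision in cross-checks). The lambda transform is instead applied
  to the *covariance*, so tip variances keep their root-to-tip path
  lengths; correlation-based variants differ on non-ultrametric trees.

Fitting is by maximum likelihood throughout, with σ² profiled out and
the single covariance parameter optimized by Brent search on the
profile likelihood (λ on [0, 1]; α on (1e−6, 50/tree-height]; r on
[−10/tree-height, 0]; the interval ends are evaluated explicitly since
Brent never touches them). ML rather than REML is used because the
model-selection step compares formulas with *different fixed effects*
by AIC, which is invalid under REML; published tables fitted by REML
will therefore be matched approximately, not digit for digit. AIC
counts fixed effects + σ² + the covariance parameter. Degenerate
covariance matrices receive one jitter of `1e-10 × mean(diag)`; if
that fails, the fit fails.

For each of the six regressions the selection procedure fits the four
models under the additive formula, the four under the interaction
formula, takes each formula's AIC-minimal model and returns the
overall minimum, with exact ties resolved toward the simpler additive
formula; the 8-fit trace is retained. Per-term p-values are
sequential (Type-I) F tests in formula order — predictor 1, locomotion,
interaction — computed from generalized residual sums of squares under
the fitted covariance; at identity covariance they reduce exactly to
classical ANOVA. Locomotion uses treatment coding with "arboreal"
(alphabetically first) as reference; the coding affects coefficients
but not AIC, likelihood or the sequential tests. Both marginal and
sequential conventions exist in the wild; the sequential one matches
the anova-style workflow the table layout implies. The reported
degrees-of-freedom pair is (n, n − k_fixed).

The move from OLS to PGLS is justified by a residual diagnostic: OLS
residuals are ordered by the tree's tip sequence and the mean absolute
difference between adjacent residuals is compared against its
permutation distribution under random orderings (999 permutations);
clustered residuals give a small observed score. The flag is raised at
the 0.05 level; on i.i.d. residuals it fires at the nominal rate and
on Brownian-simulated residuals on a 38-tip tree it fires in well over
80% of replicates.

## PEQ

The classical encephalization quotient divides observed endocranial
volume by Jerison's expectation `0.12 M^0.67`. The phylogenetic EQ
replaces the reference line with the PGLS allometry of log10
endocranial volume on log10 body mass fitted on the sample itself
under the AIC-selected covariance model: `PEQ = E / (a M^b)` with
`a = 10^intercept`. The exponent `b` is unit-free; the coefficient `a`
depends on the units (grams and mm³ here), so cross-study comparisons
of `a` require the same convention. Because the PGLS intercept is a
phylogenetically weighted mean, the geometric mean of PEQ over the
fitting sample is close to, but not exactly, 1.

## Permutation tests

The K-sample Fisher–Pitman test uses the group-sum linear statistic
with its exact permutation moments; the quadratic form
`(T − μ)' Σ⁻ (T − μ)` (generalized inverse, rank k − 1) is referred to
the χ² distribution. Pairwise comparisons use the standardized
two-sample statistic with a two-sided normal p-value and
Benjamini–Hochberg adjustment across the 10 pairs. An
exact-enumeration mode over all label assignments exists for total
n ≤ 12 and serves as the oracle in the tests. The χ² approximation is
good at the study's n = 37–38 and already serviceable at n ≈ 8–10
(observed agreement with enumeration within a few hundredths), but it
degrades sharply below that — on a 2 + 2 example the exact p is 1/3
against an asymptotic 0.12 — so small-sample conclusions should rely
on the enumeration mode. Preconditions follow the conventional route:
Shapiro–Wilk on group-centred values; if non-normal, a Levene test on
median-centred absolute deviations (the Brown–Forsythe variant;
mean-centring by flag), otherwise Bartlett's test. A failed
homogeneity check attaches a warning to the result instead of
refusing to compute — the neocortex percentage is the variable for
which this caution typically matters.

## RRPP

The non-phylogenetic ANOVA permutes reduced-model residuals: for each
term in sequence, the term-excluded model is fitted, its residuals are
permuted uniformly at random and added back to the reduced fitted
values, and the term's F statistic is recomputed. With the identity
permutation included as iteration 0, `p = (#{F* ≥ F} + 1)/(iter + 1)`,
so p is never 0 and a fixed seed gives bit-identical results. Sums of
squares are Type I in formula order, consistent with the PGLS tests.
Post-hoc statistics are absolute distances between least-squares
means evaluated at the mean of the continuous predictor
(slope-adjusted automatically when interaction columns are present),
with the null built from residuals of the no-group reduced model.
Pairwise p-values are reported unadjusted, mirroring the convention of
published post-hoc tables; BH-adjusted values are appended. The
default is 999 iterations; 1000 total evaluations give a Monte-Carlo
standard error below 0.01 for p ≈ 0.05.

## Ancestral reconstruction

**Continuous traits.** ML reconstruction under Brownian motion solves
the weighted tree-Laplacian system (edge weights 1/branch length, tips
clamped), whose solution equals the per-node re-rooted GLS estimates;
the root satisfies `(1'C⁻¹1)⁻¹ 1'C⁻¹ x`. Reconstruction assumes
Brownian motion regardless of which covariance model the regression
stage selected — the convention of the standard tooling — and the log
notes when a trait's regression chose OU or lambda. Reconstructed
traits are PEQ, the PGLS allometric residuals (the documented reading
of "residuals" among the mapped characters), log10 brain and body
size, and the three component percentages; the petrosal percentage
runs on the tree pruned of the species lacking that measurement.
Estimates are convex combinations of tip values and so stay within the
observed range.

**Locomotion.** A five-state equal-rates Markov model (off-diagonals
q, diagonals −4q) is fitted by the pruning algorithm with a uniform
root prior (a stationary-prior flag exists) and Brent optimization of
q; the equal-rates choice deliberately assumes no directionality of
locomotor change. Stochastic character maps then sample joint node
states root-down from the tip-conditional distribution and fill in
each edge's substitution history conditioned on its endpoints —
rejection sampling with a budget of 100 attempts, falling back to
uniformization (the ER jump chain has zero diagonal, so every sampled
event is a real change; the fallback count is logged). Node state
probabilities are frequencies across 1000 maps; per-map change counts
and per-state dwell times are exported alongside.

## The synthetic-data generator

The study's measurement table lives in its article supplement and is
not redistributed here, so the package ships a generator that emulates
the study design with known ground truth: a birth–death tree
(birth 0.12, death 0.06 /Myr, origin 53 Ma) conditioned on 25 extant
plus 13 fossil tips with Eocene–Miocene (5–50 Ma) extinction times;
an ER locomotor character at q = 0.01/Myr, resampled until all five
categories are observed (as in the study sample); log10 body mass by
Brownian motion (root 2.5, tip SD 0.5); log10 endocranial volume as
`log10(0.42) + 0.57 log10 M` plus per-category offsets (fossorial
−2 residual SD, arboreal +1 residual SD) plus λ = 0.72-transformed
noise scaled to a tip SD of 0.103; and component percentages simulated
on the logit scale (root baselines Neo 18.3%, PL 1.25%, OB 5.8%; tip
logit SD 0.25; modest category offsets, e.g. fossorial −0.3 for
neocortex and petrosal lobules) so the (0, 100) bounds and the
`SA_N ≤ SA_E`, `V < E` table invariants hold by construction. One
extant glider lacks the petrosal measurement, reproducing the n = 37
petrosal subset. Fossil age bins are 2–5 Myr wide around the true age.
The rate, offset and noise values not printed in any table were chosen
once as field-realistic and are not revisited.

What passing tests on these data do **not** show: the generator has no
measurement error, no correlation between locomotion and body mass, no
among-lineage rate heterogeneity beyond the lambda transform, and
clade structure that differs from the real tree — so recovering the
generating values here validates the estimators, not the biology of
any particular dataset.

## Numerical choices and limitations

* Node ids follow the standard tips-first numbering with the root at
  n + 1, stable across Newick round trips; exported node tables key on
  these ids plus a clade-span label.
* Polytomies are accepted as hard; trees must be rooted with a single
  root node and non-negative branch lengths.
* Profile optima are verified against dense parameter grids in the
  tests; likelihood ties at a model boundary (e.g. λ̂ = 1 vs Brownian)
  are resolved by AIC's parameter-count penalty.
* The exact-enumeration permutation mode is O(multinomial) and capped
  at n = 12.
* Typical problem sizes: 38 tips, 100 calibrations, 999 RRPP
  iterations, 1000 maps — a full pipeline run takes seconds; the test
  suite's simulation studies use 25–200 replicates per claim.
* Tree-dependent quantities (root reconstructions, simmap
  probabilities, regression λ̂) vary across calibration seeds; the
  pipeline reports single-seed values and the 100-tree set is exported
  for sensitivity analysis.
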