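# sciurognath

Phylogenetic comparative analysis of brain size and locomotion in
squirrels and their relatives (Sciuromorpha), built as a reusable,
tested R pipeline. The scientific question: once body size and shared
ancestry are accounted for, does locomotor behaviour — arboreal,
fossorial, gliding, scansorial or terrestrial — predict the size of
the brain and of three functionally interpretable regions visible on
endocasts (neocortex, petrosal lobules, olfactory bulbs), across a
sample that mixes extant species with Eocene–Miocene fossils?

It is written for palaeoneurologists and comparative biologists who
have a per-species measurement table (body mass, endocranial volume
and surface, component volumes/surfaces), a rooted topology and
stratigraphic age bins for the fossil tips, and who want the full
analysis — calibration through ancestral states — to be reproducible
from one seed.

## The models at the core

* **Time-calibration.** Fossil tip ages are drawn uniformly within
  their stratigraphic bins; node ages are built root-ward with a
  minimum branch length (0.1 Myr) plus stochastic increments. One
  hundred calibrated trees are averaged by per-node mean ages.
* **PGLS.** Generalized least squares with phylogenetic covariance
  `V(θ)` under four evolutionary models — Brownian (`V = C`, the
  shared-path matrix), Pagel's lambda (off-diagonals × λ), early
  burst (edges rescaled by `(e^{rt₁} − e^{rt₀})/r`, r ≤ 0) and
  stationary Ornstein–Uhlenbeck (`corr = e^{−α d}`); β̂ =
  (X'V⁻¹X)⁻¹X'V⁻¹y with the model parameter profiled by ML and the
  fit chosen by AIC over two formulas × four models. Sequential
  (Type-I) F tests give per-term p-values.
* **PEQ.** The phylogenetic encephalization quotient
  `PEQ = E / (a M^b)` with `a, b` from the sample's own PGLS allometry
  (versus Jerison's classical `EQ = E / (0.12 M^{0.67})`).
* **Fisher–Pitman permutation tests.** Asymptotic K-sample χ² from the
  exact permutation moments of group sums, pairwise standardized
  statistics with Benjamini–Hochberg adjustment, and an
  exact-enumeration oracle for small n.
* **RRPP.** Non-phylogenetic ANOVA by residual randomization
  (permute reduced-model residuals, refit, recount F), with post-hoc
  least-squares-mean distances.
* **Ancestral states.** Continuous traits by ML under Brownian motion
  (re-rooted GLS estimates); locomotion by stochastic character
  mapping under an ML-fitted equal-rates Markov model (1000 maps).

A synthetic-data module generates study-shaped datasets (38 species,
known allometry b = 0.57, λ = 0.72, residual SD 0.103, root component
baselines Neo 18.3%, PL 1.25%, OB 5.8%) so every stage is testable
with known ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
synthetic dataset (replace the files under `results/data/` with your
own CSV/Newick inputs to analyse real measurements):

```sh
Rscript analysis/01_simulate_dataset.R
Rscript analysis/02_calibrate_trees.R
Rscript analysis/03_allometry_peq.R
Rscript analysis/04_group_tests.R
Rscript analysis/05_pgls_regressions.R
Rscript analysis/06_rrpp_posthoc.R
Rscript analysis/07_ancestral_states.R
Rscript analysis/08_topology_sensitivity.R
```

Stage 3 prints the fitted allometry, e.g.

```
E_c = 0.2623 (Body mass)^0.6812  [ou model; mass g, volume mm^3]
PEQ range 0.52-1.82; highest: sp15, lowest: sp30
```

meaning the expected endocranial volume for a species of mass M grams
is `0.2623 M^0.6812` mm³ and each species' PEQ is its observed volume
divided by that expectation (the generating exponent for this dataset
was 0.57; a single 38-species replicate estimates it with appreciable
sampling error). Stage 4 prints the permutation block,

```
PEQ      chi^2 = 20.028, df = 4, p = 0.0004932  [bartlett route, variances homogeneous]
```

a five-group Fisher–Pitman test: locomotor categories differ in
relative brain size. Stage 7 reconstructs the ancestral states,

```
Root reconstruction: Neo 19.6%, OB 6.0%, PL 1.24%, PEQ 0.99
Mk-ER rate q = 0.01163 /Myr; mean 17.5 state changes per map
```

the first line being the ML estimates at the root of the average
calibrated tree (this dataset was generated from root baselines
Neo 18.3%, PL 1.25%, OB 5.8%), the second the fitted equal-rates
transition rate and the posterior mean number of locomotor changes
across the 1000 sampled character maps. Exported tables land in
`results/`: `table1.csv` (permutation blocks), `table2.csv` (six
selected PGLS fits with λ, RSE and sequential p-values),
`table3.csv` (RRPP post-hoc pairwise p-values), `peq.csv`,
`asr_nodes.csv`/`asr_nodes_pl.csv`, `simmap_nodes.csv`.

In code, the same pipeline is one call:

```r
library(sciurognath)
ds  <- simulate_dataset(synth_config(seed = 2026))
cfg <- run_config(ds$traits, ds$tree, ds$age_bins,
                  out_dir = "results/run", seed = 2026)
bundle <- run_full_analysis(cfg)
bundle$allometry
bundle$simmap
```

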