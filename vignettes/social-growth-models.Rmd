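---
title: "Social animal models for growth with pair-specific interaction degrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Social animal models for growth with pair-specific interaction degrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(penIGE)
```

## The problem

When pigs are fattened in groups, an animal's growth is shaped not only by
its own genes but by the genes of its pen mates: competition at a
single-space feeder, displacement, and social stress all transmit one
animal's genotype into another animal's phenotype. Ignoring these indirect
genetic effects (IGEs) biases genetic evaluation of average daily gain (ADG)
and can select, inadvertently, for aggressive animals. `penIGE` implements a
family of Gaussian mixed models for ADG in pen-housed animals:

* **AM** — the classical animal model,
  `y = Xb + Z_p p + Z_a a + e`, with batch, initial age, final age and pigs
  per pen as systematic effects, a random pen effect and the direct additive
  genetic effect with pedigree covariance `A σ²_a`.

* **AM-IGE** — the social animal model. Each record also receives the
  social (indirect) genetic effects of its `n − 1` pen mates through a 0/1
  incidence matrix: `y = Xb + Z_p p + Z_a a_D + Z_s a_S + e`. The direct and
  social effects are jointly Gaussian with covariance `G ⊗ A`, where `G` is
  the 2×2 direct/social genetic covariance matrix.

* **AM-IGE_i** — the same model with a *pair-specific* degree of
  interaction: the 0/1 incidence is replaced by `C_s`, whose entry for a
  pair of pen mates is the standardized Euclidean distance between their
  feeding-behaviour phenotypes. Animals far apart in feeding behaviour
  (e.g., a fast, frequent eater penned with a slow, monopolising one) are
  assumed to interact — compete — more strongly than behaviourally similar
  animals.

## Feeding behaviour as a proxy for social structure

Four traits are derived from electronic single-space feeder visits, after
bucketing visits into 1-hour blocks and merging sub-minute re-entries within
a block (hardware artefacts of these feeders):

| trait | definition | units |
|-------|------------|-------|
| FR | total intake / occupation time | g/min |
| FF | visits per day | 1/day |
| OT | trough occupation per day | min/day |
| FInt | mean gap between consecutive visits within a day | min |

The traits are phenotypically inter-correlated (fast eaters visit often,
with short intervals, and occupy the feeder less) and their within-pen
rankings are stable across consecutive 2-week periods, which is what
justifies using them to define a fixed social structure for the fattening
period. `rank_stability()` quantifies this with Spearman correlations
between consecutive periods.

Interaction degrees are built in two steps (`interaction_matrix()`): each
trait is standardized globally over all phenotyped animals using the
population (n-denominator) SD; pair distances are `|z_i − z_j|` for a single
trait or the Euclidean norm over all four; and the distances of all
within-pen pairs in the data set are then standardized again (mean 0, SD 1
over pairs). Entries for animals in different pens are 0. Negative entries
simply mean "more similar than the average pair" and are retained with their
sign; the variance partition below is evaluated at quartiles of this centred
distribution. Whether the original study standardized traits globally or
within pen is not stated in its text; we standardize globally, which leaves
the resulting `C_s` invariant to the trait-standardization convention for
single-trait modes (only the *relative* distances matter after the second
standardization).

## Variance partition

With group size `n`, mean within-pen additive relationship `r` and
interaction degree `c`, the package uses

* total breeding value `TBV_i = a_{D,i} + Σ_j c_{ij} a_{S,i}` (the sum of
  the animal's expressed interaction coefficients; `(n−1) a_S` in the
  classical case),
* total heritable variance
  `σ²_TBV = σ²_D + 2c(n−1) σ_DS + c²(n−1)² σ²_S`,
* total phenotypic variance
  `σ²_P = σ²_D + c²(n−1) σ²_S + r [2c(n−1) σ_DS + c²(n−1)(n−2) σ²_S] +
  σ²_pen + σ²_e`,
* `T² = σ²_TBV / σ²_P` (which may exceed 1), and `h² = σ²_D / σ²_P`.

The degree-dependent forms generalize the classical social-model variance
algebra by inserting `c` wherever `(n−1)` multiplies a social term; the
classical expressions are recovered at `c = 1`, and `c = 0` (the mean of the
centred degree scale) reduces `σ²_TBV` to `σ²_D`. The original publication
shows these expressions only as unrendered figure placeholders, so this is a
reconstruction from its verbal description and the underlying social-model
literature; `t2_at_quartiles()` flags its outputs accordingly by reporting
the quartiles used. Since pen sizes vary (10–14), `n` defaults to the mean
pen size; `r` defaults to the pedigree-computed mean within-pen relationship.

Derived parameters are always computed **sample-wise** along the posterior
chain and then summarized (`genetic_parameter_report()`); for skewed chains
this differs materially from plugging posterior means into the formulas.

## Estimation

**Gibbs sampling** (`gibbs_sampler()`, compiled core): single-site updates
for fixed and pen effects; each animal's `(a_D, a_S)` pair is updated as a
joint 2×2 block whose prior precision is `G⁻¹ ⊗ A⁻¹` (effect-major
stacking, mathematically identical to the animal-major `A ⊗ G` form);
`σ²_pen` and `σ²_e` from scaled inverse-chi-square full conditionals under
bounded-flat priors (upper bound 10⁶ × phenotypic variance, which makes the
"flat" priors proper); `G` from its inverse-Wishart full conditional under a
flat prior — scale equal to the cross-products of the genetic effects in the
`A⁻¹` metric and degrees of freedom `q − 3` — with rejection of
numerically non-positive-definite draws. Chains are reproducible from the
seed. The default chain (50 000 iterations, 10 000 burn-in, thinning 10) is
a test-scale protocol; production-scale chains of millions of samples are a
configuration choice, not a code change.

**EM-REML** (`em_reml()`) iterates expectation–maximization updates on
Henderson's mixed-model equations, assembled densely in the `1/σ²_e`
scaling so that the inverse coefficient matrix directly supplies the
prediction-error traces. It stops when the largest relative change falls
below `1e-6` (default) or after `maxit` iterations, returning the last
iterate flagged if unconverged. EM's asymptotic convergence on small
variance components is slow — hundreds of iterations are normal — but the
fixed point is exact: on test data the estimates coincide with a direct
dense REML likelihood optimization to at least four decimals. The estimator
serves as a likelihood-based cross-check of the Bayesian machinery, the same
role it plays in the original analysis.

## Model comparison

Four criteria, mirroring the study's workflow (`run_experiment()` ties them
together):

1. **Accuracy**: posterior SDs of the genetic parameters.
2. **DIC** (`dic()`): conditional-deviance DIC — the deviance conditions on
   location effects and `σ²_e`, the convention of the Gibbs-sampling
   software family used for this model class, with
   `pD = mean(D) − D(posterior means)`.
3. **Cross-validation** (`make_folds()`, `cross_validate()`): 8 folds, each
   holding out exactly one record per pen, so every validation set has as
   many records as pens and no record is held out twice. Variance
   components are refitted per fold (the statistically clean choice; the
   original text is silent on this), usually at reduced chain length.
   Held-out ADG is predicted from fixed effects, the pen effect, the
   animal's own direct breeding value and its pen mates' social values
   weighted by the interaction coefficients — which are computed from
   behaviour phenotypes, inputs rather than responses, and hence available
   for held-out animals.
4. **Ranking agreement**: percentage of coincidence among the top 10% of
   animals by EBV/TBV (ties broken by stable id order, set size rounded,
   minimum 1) and rank correlations of the full rankings, plus the
   correlations among DBV, SBV and TBV.

## The synthetic study generator

No data accompany the original study, so `simulate_dataset()` generates a
population with the same design: 57 pens of 10–14 phenotyped animals
(≈ 663 pigs) in 6 batches, sired by a few tens of boars. Its defaults *are*
the study conditions the analysis assumes:

* variance components `σ²_D = 0.46`, `σ²_S = 0.004`, direct–social genetic
  correlation `−0.39` (the covariance is derived from the printed
  correlation), with `σ²_pen = 0.10` and `σ²_e = 0.42` chosen so the
  animal-model heritability is ≈ 0.47;
* ADG is expressed in hg/day (mean ≈ 9, i.e. ≈ 900 g/day) so that the
  variance components sit on the scale genetic parameters are reported on;
* behaviour traits follow a stationary multivariate AR(1) across 2-week
  periods whose cross-sectional correlations hit the published values
  (FR–FF 0.56, FR–FInt −0.60, FF–FInt −0.64, FR–OT −0.20). The two pairs
  never printed (FF–OT, OT–FInt) are set to −0.25 and +0.30 from the
  dominance narrative (calm, dominant animals visit rarely, occupy long,
  pause long); the completed matrix is checked for positive definiteness.
  The AR(1) coefficient 0.78 targets consecutive-period rank correlations
  in the published 0.67–0.86 band;
* absolute behaviour scales (FR ≈ 35 g/min, FF ≈ 12/day, OT ≈ 80 min/day,
  FInt ≈ 90 min) are conventions — the published descriptive table is not
  machine-readable — and only the correlation structure is constrained;
* genetic effects are drawn by pedigree-recursive Mendelian sampling
  (founders from `N(0, G)`; offspring from the parent mean plus a Mendelian
  residual scaled by `0.5 − 0.25(F_s + F_d)`), which realizes `G ⊗ A`
  without factorizing a dense matrix;
* all true effects are stored, so phenotypes reconstruct exactly and
  recovery tests can compare against the truth.

Pens are filled litter-wise with a partial shuffle (`pen_mixing = 0.2`),
which reproduces the mean within-pen additive relationship of ≈ 0.13
observed in litter-structured herds; family members sharing pens is also
what keeps the direct genetic and residual variances mutually identifiable
at this design. What the generator deliberately does **not** emulate:
genetic signal in the behaviour traits themselves; feeder-hardware failure
modes beyond sub-minute re-entries; and selection or non-random mating in
the pedigree. Passing
tests therefore validate the estimation machinery under the model's own
assumptions, not the biology of any particular herd.

## Numerical choices and degenerate inputs

* Unknown parents are unrelated founders; no genetic groups. Inbreeding is
  computed (Meuwissen–Luo) and enters both `A` and its sparse inverse —
  whether the original `A` accounted for inbreeding is unstated, but the
  exactness of `A⁻¹ A = I` requires it.
* Population-SD (n-denominator) standardization is used for traits and
  distances, matching "mean and SD across all mate pairs".
* The covariate pigs-per-pen is centred; if it is constant (equal-size
  pens) or batch has one level, the term is dropped rather than failing on
  rank deficiency. Genuine collinearity among user covariates is an error
  naming the columns.
* Pens with a single phenotyped animal get zero interaction rows (warning);
  pens with fewer records than folds contribute each record to one fold.
* A `G` draw that is numerically non-PD is rejected and redrawn (up to 50
  times, then the previous value is kept and counted); variance draws are
  clamped to the bounded-flat prior support.
* Quartiles of the interaction degrees use the standard type-7 empirical
  quantile; top-fraction sets round to the nearest integer, minimum one
  animal, ties broken by animal id.

## Problem sizes used by the test suite

The automated checks run at desk scale, chosen once: the replicate-based
EM-REML validation uses 10 replicates of 720 animals (60 pens × 12) with
500 EM iterations; sampler recovery uses 10 seeds of the full default design
(57 pens, ≈ 660 animals) at the default 50k/10k/10 chain; model-comparison
direction uses 20 (DIC) and 10 (cross-validation) replicates of a 24-pen
design with a ten-fold stronger social variance, at short chains. These
sizes trade Monte Carlo precision for runtime; all checks are interval- or
direction-based, not point comparisons.

## Limitations

Single records per animal; Gaussian traits only; one social effect per
animal (no maternal or dominance effects); dense EM-REML limited to a few
thousand equations; the behaviour-distance hypothesis is taken as given —
the package quantifies how much it improves fit and prediction, not whether
distance is the mechanistically correct kernel.
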