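---
title: "Hierarchical symbolic regression for TLC retention: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical symbolic regression for TLC retention: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uhsr)
```

## The modeling problem

Thin-layer chromatography (TLC) measures a retardation factor Rf in [0, 1]
for a solute spotted on a silica plate and developed in a solvent mixture.
Rf summarizes a competition: the polar stationary phase retains the solute,
the mobile phase elutes it.  The package models Rf as a function of a
23-dimensional, chemist-readable feature vector per measurement:

* five volume fractions of the mobile-phase components (n-hexane, ethyl
  acetate, dichloromethane, methanol, diethyl ether), binary mixtures in
  practice;
* sixteen functional-group counts of the solute (phenolic and alcoholic
  hydroxyl, aldehyde, carboxylic acid, ester, ketone, ether, cyano, amine,
  nitro, amide, methyl, and the four halogens);
* the benzene-ring count and the dipole moment (Debye), which stand in for
  how the groups are distributed over the scaffold.

Rather than fitting one black-box map, the package learns scalar
*retention indices* that factor the problem the way a chemist would: a
solvent index psi (net eluent strength on silica), a solute index xi
(effective solute polarity as expressed in TLC), and a further split of xi
into a functional-group index beta (what groups are present) and a
distribution index alpha (how they are arranged), with beta refined into
five subgroup indices gamma1..gamma5.  Concise equations linking the
indices are then recovered by symbolic regression.

## Modular networks and the latent gauge

Each stage of the hierarchy is a modular feed-forward network: the feature
vector is partitioned into groups, each group feeds its own sub-model (two
hidden layers of 50 LeakyReLU units by default) emitting one scalar latent,
and a small head maps the latents through a final sigmoid to predicted Rf.
Because a latent's receptive field is restricted to its group by
construction, group-locality is exact, not approximate: two inputs that
agree on a group produce identical values of that group's latent.

Training minimizes mean-squared error on Rf with Adam (learning rate 0.01,
batch size 2048, 1000 epochs by default); a seeded 10% validation split is
used only to select the best checkpoint.  All randomness (initialization,
split, shuffling) derives from one seed, so runs are bit-reproducible on a
platform.

A scalar latent is identified only up to an invertible transform: the head
can undo any re-labeling, so two equally accurate networks can carry
latents that differ by arbitrary monotone — or even non-monotone —
re-parameterizations.  Left unfixed, this gauge freedom makes downstream
equations ill-defined.  The package fixes the gauge in three steps:

1. **Partial-dependence calibration.**  After training, each latent is
   re-expressed as the average *pre-sigmoid* head output (the logit of
   predicted Rf) as that latent varies over its training range with the
   other latents held at observed values.  The curve is tabulated on a
   101-point grid against 256 evenly spaced reference rows and applied by
   linear interpolation.  This measures every latent in the same physical
   units — the additive logit-Rf contribution it induces — which is the
   scale the governing equations are written on.  The transform depends
   only on the latent's own value, so group-locality is preserved exactly.
2. **Standardization** to mean 0, variance 1 over the training records
   (stored as an affine transform, exactly invertible).
3. **Sign canonicalization**: flips make stated references non-negative —
   psi correlates positively with the methanol fraction, xi with Rf, alpha
   with the dipole moment; beta probes amide above iodine; each gamma
   probes its leading functional group above the zero probe.  The
   operation is idempotent and records its flips.

One-hot probing reads a trained sub-model at a basis input (a pure solvent,
or a single functional group set to 1): the probe value is that
component's standardized latent contribution, and probe orderings are the
package's quantitative polarity ranking of solvents and functional groups.

## The symbolic-regression engine

Equations are discovered by genetic programming over expression trees with
primitives drawn from `+ - * /(protected) exp log(protected)`, variables,
and real constants; complexity is the node count.  The engine maintains the
best expression at every complexity and reports the non-dominated
(complexity, loss) Pareto front.  Defaults: population 1000, up to 40
generations, tournament size 10, 30% crossover with the rest split over
subtree, point, constant-jitter, insert and hoist mutations, maximum
complexity 30.

Two refinements matter in practice:

* **Constant optimization.**  New per-complexity bests get their constants
  refined by Levenberg–Marquardt least squares (via minpack.lm); a refined
  tree is kept only if its loss does not increase, so the step is monotone.
* **Greedy memetic expansion.**  Periodically (every third generation) the
  engine also grows the current best member by the single most helpful
  additive term, chosen by refitting all constants and accepted while it
  improves the loss by at least 1%; plain linear terms `c*v` form a first
  tier and product terms `c*v*w` a second, tried only when no linear term
  helps.
  Evolution explores freely; the expansion provides a fast, deterministic
  lane to exact additive structure that plain mutation reaches only
  slowly within the complexity cap.

Protected operators never emit non-finite values — division by a
near-zero denominator and logarithms of non-positive arguments produce a
large-magnitude sentinel — and any candidate that triggers protection is
assigned worst-case fitness rather than silently rewritten.

Equation selection is parsimony-based: the least complex front member
whose loss is within a relative tolerance of the front's best (with a
1e-12 absolute floor so numerically-zero losses tie), ties broken by lower
loss.  The engine default tolerance is 0.01.  The *pipeline* selects at
0.10: on noisy targets, members within ~10% of the best loss are
statistically indistinguishable, and the simpler form is the point of the
method.  Once a near-exact fit (loss below 1e-12) appears, evolution
continues for 8 more generations — giving simplifying mutations a chance
to find the minimal exact form — and then stops.

Fits are deterministic under the configured seed.  Trees render to a
canonical infix string (commutative chains flattened and sorted, constants
last in sums) so equal expressions print identically.

## Reference equations and the synthetic generator

The package ships the governing equations as executable fixtures:

* `rf_governing(psi, xi) = sigma(5.15 psi + 5.15 xi + 1.55)`;
* `psi_reference`: the linear solvent equation
  `-1.37 Hex - 0.20 EA - 1.02 DCM + 4.65 MeOH - 0.45 Et2O` (no intercept;
  pure-component evaluation returns each coefficient);
* `xi_reference(alpha, beta) = 0.37 alpha - 0.35 beta - alpha beta + 0.69`;
* the printed one-hot probe weights of the sixteen functional groups
  (amide 1.43 down to iodine -2.97), and their linear combination
  `fg_probe_linear` as the unambiguous beta oracle;
* interpretive transcriptions `alpha_reference` / `beta_reference` of the
  deeper alpha/beta/gamma equations.  Their typeset source is ambiguous;
  the package implements one documented reading (e.g. the gamma3 ester
  clause as a ratio) and labels it interpretive.  No test uses them as an
  oracle; they exist for value-flow tracing and decomposition analysis.

The synthetic generator (`gen_dataset`) uses exactly this chain as its
mechanism — there is no second implementation.  Solvent compositions come
from a 17-point grid over the three binary systems (hexane/ethyl acetate,
hexane/diethyl ether, methanol/dichloromethane), with methanol capped at
10 volume-percent and system weights chosen so the five marginal means
match the observed feature statistics (hexane 0.36, ethyl acetate 0.15,
dichloromethane 0.40, methanol 0.014, diethyl ether 0.071).  In grid mode
records are allocated over the grid by largest-remainder rounding
(n = 17 yields each composition exactly once); sampling mode draws at
random.  Functional-group counts are truncated Poisson (cap 3) at the
observed means; the benzene-ring count is drawn on 0..3 with mean 1.12 and
the dipole moment is normal(1.34, 0.74) truncated at zero.  The solute
indices are standardized over the sample: beta from the linear probe
weights, alpha from the affine surrogate `0.5 DM + 0.5 NBen` (the
interpretive alpha transcription is deliberately not used as ground
truth).  Observed Rf adds Gaussian noise on the logit scale
(`sigma(logit(rf_true) + eps)`), keeping values inside (0, 1); default
noise sd 0.05 and n = 3000, a desk-scale stand-in for a
few-thousand-measurement robotic screen.

What the generator does *not* emulate: plate-to-plate, temperature and
humidity variability; correlated functional-group co-occurrence; realistic
SMILES (counts are drawn directly); and any deviation of the true
mechanism from the reference equations.  Passing recovery tests therefore
demonstrates that the pipeline can re-discover a known mechanism of this
form at realistic noise — not that real TLC data obey it.

## Pipeline choices and numerical details

`run_uhsr` holds out a seeded 10% test split, trains the three stages on
the rest, and runs four symbolic regressions on the standardized latents:
logit(Rf) against (psi, xi); psi against the five solvent fractions; xi
against (alpha, beta); beta against (gamma1..gamma5).  Reported equations
live in the standardized gauge, with the affine transforms published
alongside so raw-gauge equations can be derived.

* **Censored extremes.**  Records with observed Rf outside (0.01, 0.99)
  are saturated at the plate bounds and carry no logit-scale information;
  they are excluded from the logit-equation fit (not clipped into it,
  which would bend the target and masquerade as a cubic term).
  Predictions and metrics still cover all records.
* **Pure-component readings.**  On compositions that sum to one, the
  solvent equation's coefficients are identified only up to a constant
  shifted between the intercept and all coefficients; evaluating a fitted
  expression at a pure composition is invariant to that gauge and is how
  coefficients are read.
* **Metrics.**  R2 uses the 1 - SS_res/SS_tot definition, RMSE the plain
  root mean square; Spearman correlations accompany them.  A zero-variance
  response yields an undefined R2, reported as missing with a flag.
* **Cross-validation** uses seeded folds of near-equal size; per-fold
  equations are reported side by side, never averaged (expression
  averaging is undefined; the interesting observation is that the *form*
  is stable while coefficients vary).
* **Solvent recommendation** ranks candidate compositions by the distance
  of predicted Rf to the 0.2–0.3 band used for preparative work, breaking
  ties toward lower methanol, since small methanol changes cause
  disproportionate polarity shifts.

Problem sizes used by the shipped tests were chosen for desk-scale
determinism: recovery of the solvent equation from 500 compositions, of
the Rf and xi equations from 2000 latent pairs, and the full pipeline at
n = 3000 with logit noise 0.05.

## Known limitations

* The interpretive alpha/beta/gamma transcriptions are one reading of an
  ambiguous source and are not claimed to match the original equations.
* Latent recovery is only up to the fixed gauge; comparisons to published
  index values are meaningful after rank or affine alignment, not
  numerically.
* The feature set targets rigid, largely sp2 scaffolds with the sixteen
  listed groups; heteroaromatics without benzene rings, fused systems and
  flexible sp3-rich molecules fall outside the featurization's design
  range.
* The GP engine's greedy expansion accelerates additive structure; deeply
  nested non-additive targets rely on the evolutionary operators alone and
  may need larger budgets.
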