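---
title: "Estimating symptom networks from ordinal questionnaires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating symptom networks from ordinal questionnaires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The model

`symptomnet` analyses comorbidity between two symptom domains — the bundled
instruments are the PHQ-9 (nine depression items) and GAD-7 (seven anxiety
items), both scored 0–3 per item — as a *network* of pairwise conditional
associations rather than as two latent disease factors. The statistical
object is a Gaussian graphical model (GGM): nodes are items, and an edge
carries the partial correlation between two items after conditioning on all
remaining items,

$$\rho_{ij\cdot} = -\frac{\kappa_{ij}}{\sqrt{\kappa_{ii}\,\kappa_{jj}}},$$

where $\kappa$ are entries of the precision (inverse covariance) matrix.
Because the items are ordinal and skewed, the input to the Gaussian
machinery is the Spearman rank correlation matrix with average-rank tie
handling (the rank-based plug-in for monotone-transformed Gaussian data);
polychoric correlations are deliberately out of scope. Rank correlation
matrices need not be positive semidefinite, so eigenvalues are clipped at a
small floor ($10^{-6}$) and the diagonal renormalized before estimation —
a deterministic, minimal repair.

The precision matrix is estimated by the graphical lasso, maximizing
$\log\det K - \mathrm{tr}(RK) - \lambda \sum_{i \ne j} |K_{ij}|$ with an
*unpenalized* diagonal, over 100 log-spaced penalties from
$\lambda_{\max}$ (the largest absolute off-diagonal correlation, where the
graph is empty) down to $0.01\,\lambda_{\max}$. The penalty is selected by
the extended BIC,

$$\mathrm{EBIC}_\gamma = -2\ell + E\log n + 4E\gamma\log p,$$

with $\gamma = 0.5$, the conventional setting that balances sensitivity
against specificity; $E$ counts edges above the solver-noise threshold
$10^{-8}$. The solver is block coordinate descent (a compiled
implementation, tolerance $10^{-6}$); at $\lambda = 0$ on positive definite
input it reproduces the plain matrix inverse, which the tests exploit as an
oracle.

## Centrality, bridges, predictability, flow

*Expected influence* (EI) is the one-step signed sum of a node's edge
weights; *bridge expected influence* (BEI) restricts the sum to edges
crossing to the other community. One-step (not two-step) sums are used
because they are the quantities whose stability the bootstrap suite
assesses. Bridge symptoms are the nodes whose **raw** BEI reaches the 80th
percentile of the BEI distribution; z-scored values are for display only.
The percentile uses the type-6 linear-interpolation convention: for
distinct scores its threshold falls strictly between order statistics, so
16 distinct scores yield exactly 3 bridge nodes, while an all-tied vector
selects every node. (The more common type-7 convention lands exactly on an
order statistic at $n = 16, p = 0.8$ and would select 4; the type-6 choice
reproduces the 3-of-16 behaviour this analysis family reports.)

*Predictability* is the in-sample $R^2$ of each item regressed (OLS) on
its network neighbours — the Gaussian special case of mixed-graphical-model
predictability, consistent with treating the 0–3 items as continuous
everywhere else. Isolated nodes get 0; collinear neighbour designs fall
back to a ridge solve with penalty $10^{-8}$. By the Markov property of a
GGM, the population value given the neighbours equals the value given all
other nodes, $1 - 1/\kappa_{ii}$ for standardized data, which the tests
verify on latent Gaussian samples.

The *flow decomposition* around a focal symptom (suicidal ideation, `D9`,
in the default pipeline) separates direct neighbours, ranked by absolute
weight, from indirect nodes layered by unweighted BFS hop distance through
nonzero edges. The layering is a faithful reconstruction of the usual flow
diagram; hop distance, not edge weight, defines the layers.

## Stability suite

Three bootstrap procedures, all with per-replicate seeds derived from one
master seed (so results are identical regardless of scheduling):

- **Edge accuracy.** Nonparametric bootstrap (resampling subjects with
  replacement, default `nboots = 2000`) rerunning the entire
  Spearman → repair → glasso → EBIC chain; percentile 95% intervals per
  edge. Replicates with degenerate resamples are dropped and counted;
  more than 10% failures abort.
- **Case-dropping stability.** For drop proportions 0.05–0.75, subjects
  are removed without replacement, the centrality is re-estimated and
  correlated with the full-sample centrality across nodes. The CS
  coefficient is the largest proportion at which the correlation reaches
  0.7 in at least 95% of resamples (both constants are config keys; the
  CS rule's 95% confidence level follows the reference description of the
  coefficient). CS ≥ 0.25 is the usual minimum, ≥ 0.5 good.
- **Difference tests.** Percentile bootstrap intervals of pairwise
  differences (edges, EI, BEI) at $\alpha = 0.05$, flagged significant
  when the interval excludes zero; deliberately uncorrected for
  multiplicity, matching the procedure's standard usage, so the flags are
  descriptive.

## The synthetic-cohort generator

Because item-level data of this kind are typically available only on
request, the package ships a generator whose defaults emulate a tinnitus
outpatient screening cohort: 566 subjects, 9 + 7 items, and per-item
thresholds calibrated so that a discretized latent standard normal
reproduces the item means (closely; SDs approximately — three thresholds
cannot match both exactly, and the mean is weighted 50:1 in the
calibration objective) of `default_item_marginals()`, including the strong
right skew of rare symptoms such as suicidal ideation (mean 0.18).

The ground truth is a sparse partial-correlation network: within-community
edges with probability 0.35, background cross-community edges with
probability 0.04, absolute weights uniform on [0.10, 0.30] with 90%
positive signs — values chosen once as realistic for item-level
psychopathology networks, where within-instrument dependence dominates and
negative conditional associations are rare. Three planted bridge symptoms
(by default `A7`, `D6`, `D7`) each receive three cross edges of weight
0.18. Positive definiteness is enforced by uniformly shrinking the
off-diagonal until the smallest eigenvalue clears 0.05, which rescales all
partial correlations equally and preserves the pattern.

Two design rules keep the benchmark honest:

- *Planted bridges dominate by construction.* Partners are assigned
  least-used-first so no partner accumulates several planted edges, and
  background cross edges of any competing node are shrunk until every
  non-planted node stays below 60% of the weakest planted bridge. The
  margin is chosen so that bridge-recovery failures can only come from the
  estimation method, not from truth-level near-ties smaller than sampling
  noise at the cohort sizes the package tests (n in the hundreds to a few
  thousand).
- *Everything flows from one master seed*, with sub-seeds per stage, so a
  cohort is bit-reproducible.

### What the generator does and does not emulate

It reproduces the marginal skew, the two-community dependence structure,
and the ordinal measurement process. It does not emulate covariate effects
(age, sex, tinnitus duration), item response theory discrimination
parameters, missing-data mechanisms (the questionnaire module implements
complete-case exclusion instead), or the *strength* of real item
intercorrelations — the synthetic truth is deliberately sparse and weak,
so synthetic Cronbach's alpha (~0.5) and mean predictability (~15–30%)
sit well below values typical of real screening cohorts (~0.9 and ~50%).
Passing recovery tests therefore shows the machinery is correct, not that
real-data results would be numerically similar.

## Numerical choices and degenerate inputs

- Ties: average ranks in Spearman; type-6 percentile in bridge selection;
  sample (n−1) variance in Cronbach's alpha and z-scores.
- Constant items abort correlation with the item named; constant
  centralities abort CS estimation (a correlation with a constant vector
  is undefined); `centrality_profile()` maps a constant metric to zero
  z-scores so that sparse networks still tabulate.
- Edge existence: |weight| > 1e−8 (solver-level zeros are true zeros).
- The EBIC sample size is the number of complete-case subjects.
- `n ≤ p` correlation inputs are rejected before estimation.

## Known limitations

- **Specificity of EBIC-glasso at large n.** With $\gamma = 0.5$ the
  EBIC-selected penalty keeps many tiny false edges once n reaches a few
  thousand: the likelihood gain of relaxing true edges drags the selected
  penalty down and spurious edges ride along (a documented property of
  this selection rule — it is not sparsistent). Ordinal discretization
  adds small spurious partial correlations (up to ≈ 0.03 asymptotically
  under the default thresholds), compounding the effect: edge-pattern
  specificity at n = 5000 averages ≈ 0.6 on default cohorts even though
  sensitivity and bridge recovery are essentially perfect. Interpret the
  *presence* of weak edges cautiously; weights and rankings are reliable.
- **Near-tied centralities are not recoverable.** When true EI gaps
  between mid-ranked nodes are of the order of the sampling noise,
  estimated ranks around those positions scramble; the package therefore
  validates EI recovery by rank correlation, not exact rank placement.
- In-sample predictability is an optimistic (non-cross-validated) measure,
  matching its standard definition in this literature.

## Problem sizes used in the test suite

The suite exercises cohorts of 200–5000 subjects, 16 nodes, bootstrap
replicate counts of 100–200 and case-dropping grids of 2–8 proportions;
the acceptance script uses the 566-subject default cohort with
`nboots = 200` (edge accuracy) and 50 resamples per drop proportion.
These sizes were chosen so the statistical contracts under test —
coverage, monotonicity, determinism, recovery — are already decisive at
small replicate counts.
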