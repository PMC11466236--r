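---
title: "Cross-lagged panel networks for NSSI, depression and anxiety: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-lagged panel networks for NSSI, depression and anxiety: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clpnet)
```

## The model

A cross-lagged panel network (CLPN) describes a set of $p$ symptoms
measured at two waves as a directed network. The edge $i \to j$ is the
coefficient $\beta_{ij}$ of wave-1 symptom $i$ in a regression of wave-2
symptom $j$ on *all* wave-1 symptoms and covariates:

$$ y_j^{(2)} = \alpha_j + \sum_{i=1}^{p} \beta_{ij}\, y_i^{(1)}
   + \gamma_j^\top z + \varepsilon_j , $$

so each edge is a lagged, mutually adjusted association. The diagonal
$\beta_{jj}$ is the autoregressive effect of a symptom on itself;
off-diagonal entries are cross-lagged effects. For the default 24-symptom
catalog (12 NSSI behaviors, 6 depression items, 6 anxiety items, all scored
0--4) there are $24^2 - 24 = 552$ cross-lagged edges.

Because the number of predictors per outcome (24 symptoms + gender) is not
small relative to typical panel sizes, each nodewise regression is fit with
an L1 (lasso) penalty,

$$ \hat\beta_j = \arg\min_\beta \tfrac{1}{2n}\,\|y_j^{(2)} - X\beta\|^2
   + \lambda_j \textstyle\sum_{k \in \text{penalized}} |\beta_k| , $$

which shrinks weak edges exactly to zero and yields a sparse, directly
interpretable network. Covariates (gender in whole-sample fits) are
unpenalized: control variables should not be shrunk away. The penalty
$\lambda_j$ is chosen per outcome by K-fold cross-validation.

Ordinal 0--4 scores are treated as continuous, the standard practice for
symptom networks; all symptom columns are z-scored within each wave
(population-sd convention, divisor $n$) so edge weights are comparable
across items. Gender-specific networks are fit by subsetting, dropping the
gender covariate.

## The solver

The nodewise lasso is solved by cyclic coordinate descent on centered
sufficient statistics ($X^\top X/n$ and $X^\top y/n$), with an active-set
strategy and warm starts along a 100-point log-spaced penalty grid. The
grid starts at $\lambda_{\max}$, the smallest penalty for which all
penalized coefficients are zero (computed after fitting the unpenalized
block freely), and descends to $10^{-4}\lambda_{\max}$. Convergence is
declared when no coefficient moves more than $10^{-7}$ in a full sweep
(at most 10,000 sweeps), and every returned solution is certified against
the L1 stationarity (KKT) conditions to within $10^{-6}$: zeroed
coefficients must have $|$partial covariance$| \le \lambda$ and active ones
must sit exactly on the subgradient. At $\lambda = 0$ the solver reproduces
ordinary least squares; at fixed $\lambda$ it agrees with an independent
lasso implementation to $10^{-6}$ (both are asserted in the test suite).

Cross-validation errors are computed from per-fold sufficient statistics,
so the cost per fold per penalty is $O(p^2)$ independent of $n$. Folds are
assigned deterministically from `cv_seed`; fixed data and configuration
give a bit-identical network.

Two selection rules are available. The default, `lambda_rule = "min"`,
takes the CV-error minimizer; it is the more sensitive rule and is what the
recovery results below rely on. The conservative one-standard-error rule
(`"one_se"`) is offered for sparser displays: on pure-noise outcomes it
returns an empty model almost always, whereas the CV-minimum rule retains a
small number of spurious edges (roughly 8--12% of the 552 cross-lagged
edges at $n = 500$ — the familiar liberality of CV-minimum lasso, which we
also observe in other lasso implementations on identical data). Users who
need strict false-positive control should prefer `"one_se"` or filter by
bootstrap stability; users interested in weak signals should keep `"min"`.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cv_folds` | 10 | CV folds for penalty selection |
| `lambda_rule` | `"min"` | CV-minimum vs one-SE penalty |
| `lambda_grid_size` | 100 | penalty grid points |
| `lambda_min_ratio` | 1e-4 | smallest/largest grid penalty |
| `penalize_covariates` | `FALSE` | shrink covariates like symptoms |
| `standardize` | `TRUE` | z-score items within wave |
| display threshold | 0.06 | strict \|weight\| cut for reporting only |

Thresholding at 0.06 is a *display* rule (`threshold_edges()`), applied
strictly (`|w| > 0.06`); estimation keeps every exactly-nonzero
coefficient.

## Derived quantities

**Expected influence.** Out-EI of node $i$ is the signed sum of its
outgoing cross-lagged weights $\sum_{j \ne i} \beta_{ij}$; in-EI of $j$ is
$\sum_{i \ne j} \beta_{ij}$. Signed sums (not absolute strength) are used
so that inhibitory edges count against a node's influence; an
absolute-value variant is available via `absolute = TRUE`. Total out-EI and
total in-EI are always equal — both are the sum of all off-diagonal
weights — which the tests assert on random networks.

**Bridge edges.** Cross-community edges (e.g., NSSI $\to$
depression/anxiety) ranked by absolute weight, with deterministic
lexicographic tie-breaks. The package reports bridge *edges* (top-k lists),
not bridge expected-influence statistics.

**Network comparison.** For two fitted networks over the same catalog:
Pearson correlation of the vectorized cross-lagged weights; the percentage
of each network's nonzero edges that are nonzero in the other (asymmetric
by construction); and the Jaccard index, shared edges over the union of
nonzero directed edges. By default an edge pair counts as shared only if
direction *and* sign agree (`match = "sign"`), since a reversed-sign edge
describes a different dynamic; direction-only matching is available because
either convention is found in applied work.

**Bootstrap accuracy.** Non-parametric subject resampling re-fits the full
CLPN — including CV penalty re-selection by default — in each replicate,
and percentile intervals are literal order statistics of the replicate
draws: with $B$ kept replicates and level $1-\alpha$, the endpoints are the
$\max(1, \lfloor \alpha B/2 \rfloor)$-th and
$\min(B, \lceil (1-\alpha/2)B \rceil)$-th sorted values. This makes the
nesting property (99% intervals contain 95% intervals edge-wise) exact.
Replicates that fail (e.g., a resample in which a rare NSSI item is
all-zero) are dropped and counted; the run aborts if more than 5% fail.

## The synthetic-data generator

No subject-level data ship with the package, so the entire pipeline is
validated against a generator with known ground truth. The generative
family is a latent multivariate normal with threshold discretization:

1. wave-1 latents $\eta^{(1)} \sim N(0, R)$ with unit variances; $R$ has
   within-community correlations 0.4 (NSSI) and 0.5 (depression, anxiety),
   0.3 between depression and anxiety, and 0.15 between NSSI and the
   emotional communities — a sign pattern consistent with scale-level
   correlations reported for this population;
2. wave-2 latents $\eta^{(2)} = B^\top \eta^{(1)} + \varepsilon$,
   $\varepsilon \sim N(0, \sigma^2 I)$ with $\sigma = 1$ on the
   standardized latent scale;
3. each latent is cut into 0--4 by per-node thresholds.

The default two-group truth encodes the study conditions the package
emulates: boys' cross-lagged edges N9$\to$D2 $= -0.57$, N9$\to$A6
$= -0.52$, N9$\to$D1 $= -0.49$, A6$\to$D2 $= 0.23$, A4$\to$D6 $= 0.14$;
girls' A4$\to$D1/D4/D6 $= 0.16/0.14/0.14$, N12$\to$D1 $= -0.31$,
N11$\to$D1 $= -0.21$; autoregressive diagonals 0.12 (boys) and 0.17
(girls); all other cross-lagged entries zero; group mix 403 boys : 481
girls. Per-item autoregressive heterogeneity is not emulated (only the
group-level means are known), and attrition between waves is out of scope.

**Zero-inflation of NSSI.** NSSI behaviors are rare: the generator
calibrates the first NSSI threshold analytically (numeric integration over
the equicorrelated block) so that the probability of *any* nonzero NSSI
item at wave 1 is 23.3%. This is implemented as a high first threshold, not
a separate hurdle process — simpler, and exact for the NSSI block
regardless of its correlations with other communities. Upper NSSI
thresholds are spaced 0.7 apart; depression/anxiety thresholds are
(0.25, 1.15, 2.0, 2.7), giving per-item means around 0.55, in line with
scale-level means of about 3.2 over six items in this population.

**Sub-seeding.** A master seed keys a stream of derived stage seeds (group
assignment, wave-1 latents, wave-2 noise), so each stage is independently
reproducible and identical `(spec, n, seed)` always regenerates the same
integer scores.

## What the generator does and does not establish

Passing recovery tests on synthetic panels shows that the estimator finds
the right signs and orderings *when the generative model is the latent
linear one above*. Real symptom data depart from it in known ways: item
distributions are not exactly threshold-normal, effects need not be linear
in the latent, and the 6-month lag may not match the causal timescale.
Recovery results should be read as software validation, not as evidence
about adolescents.

Two quantitative consequences of the design are worth stating plainly,
because they shape what can be expected of any estimator on such data:

- **Attenuation.** Discretizing a rare behavior (per-item endorsement
  around 3.5% after the 23.3% any-NSSI calibration) caps the correlation
  between the observed item and its latent at about 0.42, so a latent
  cross-lagged weight of $-0.57$ corresponds to an observed-scale
  (pseudo-true) coefficient of about $-0.085$ — the value an unpenalized
  fit converges to at very large $n$. Sign recovery at $n = 884$ is
  nevertheless reliable (the acceptance suite measures $\ge 90\%$ sign
  agreement on edges with true $|\beta| \ge 0.2$).
- **Ranking instability.** The three strongest boys' bridges are nearly
  tied in truth ($-0.57/-0.52/-0.49$), and attenuation compresses their
  observed-scale gaps below the sampling noise of $n = 884$ (coefficient
  SEs $\approx 0.03$). Identifying *which* of them ranks first is therefore
  unstable in any single sample, even though the set of strong bridges is
  recovered. The package reports top-k bridge lists rather than a single
  winner for this reason.

**Coverage estimand.** For the bootstrap coverage study on the compact
six-node truth (`toy_ground_truth()`), the target of inference is the
*pseudo-true* coefficient — the large-sample limit of the fitted procedure
on the standardized ordinal scale, computed by an unpenalized fit at
$n = 50{,}000$ — not the latent-scale $B$. Discretization attenuates the
latent weights (by roughly 0.78 under the toy truth's balanced thresholds),
so intervals for the observed-scale procedure cannot be expected to cover
latent-scale values; coverage against the procedure's own estimand is the
well-posed check.

## Numerical choices and degenerate inputs

- Zero-variance symptom columns abort standardization with an error naming
  the node (inside bootstrap replicates this becomes a counted failure).
- Columns with (numerically) zero Gram diagonal keep a zero coefficient.
- A degenerate outcome whose penalized covariances are all zero gets a
  small flat penalty grid rather than a division by zero.
- Ties in bridge/threshold rankings break lexicographically by node id, so
  all orderings are deterministic.
- Percentages in the exclusion report are truncated (not rounded) to two
  decimals, the convention of sample-accounting tables this report mirrors.

## Problem sizes used in the test suite

The suite exercises the design scale where the property depends on it:
recovery runs 10 seeds of per-group panels at $n = 884$; prevalence
calibration uses 20 seeds at $n = 884$; the null-network property uses 20
seeds at $n = 500$; the bootstrap coverage study uses 200 datasets of
$n = 300$ from the six-node truth with 200 replicates each; bootstrap
mechanics (order statistics, nesting, determinism) use 50--80 replicates on
small panels. The default of 1,000 bootstrap replicates is intended for
real analyses.

## Known limitations

- Two waves, two groups, listwise deletion only; no imputation, attrition
  modelling, or multi-wave extensions.
- Ordinal items are regressed as continuous; no ordinal-link models.
- Percentile bootstrap intervals only (no BCa), and lasso shrinkage means
  intervals are for the penalized procedure, not debiased coefficients.
- Within-wave (contemporaneous) networks are not estimated; the model
  reports lagged edges only.
- The CV-minimum default trades some false positives for sensitivity; see
  the solver section for the conservative alternative.
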