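---
title: "Estimating and comparing partial-correlation networks from ordinal questionnaire data"
author: "ordnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing partial-correlation networks from ordinal questionnaire data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Quality-of-life questionnaires such as the S-QoL18 summarize a patient's
self-reported experience into a small number of ordinal dimension scores
(self-esteem, romantic life, resilience, psychological well-being, physical
well-being, friendships, family relationships, autonomy). Network
psychometrics treats these dimensions not as reflections of a single latent
quantity but as a system of mutually interacting components: nodes in an
undirected network whose edges quantify the *conditional* association
between two dimensions after controlling for all the others. `ordnet`
implements the full analysis chain this view requires — estimation of a
regularized Gaussian graphical model (GGM) from ordinal data, centrality
analysis, bootstrap accuracy and stability checks, and permutation-based
comparison of networks between diagnostic groups — together with a
synthetic-data generator that provides ground truth for every stage.

# The model

## Latent-normal measurement: polychoric correlations

Ordinal scores with a handful of response options violate the multivariate
normality a GGM assumes. We therefore model each observed ordinal variable
as a discretized version of a latent standard-normal variable: category
$k$ is observed when the latent score falls between thresholds
$\tau_{k-1}$ and $\tau_k$. The *polychoric correlation* of two variables
is the correlation of their latent normals.

`polychoric_matrix()` uses the classical two-step estimator: thresholds
are fixed at $\tau_k = \Phi^{-1}(\hat F_k)$ from the marginal cumulative
proportions (`estimate_thresholds()`), and each pairwise $\rho$ then
maximizes the contingency-table likelihood
$\sum_{ij} n_{ij}\log P_{ij}(\rho)$, where $P_{ij}$ is the
bivariate-normal rectangle probability between consecutive thresholds.
Choices that matter:

* **Two-step rather than full joint ML.** The two estimators agree to
  well within sampling error and two-step is orders of magnitude cheaper,
  which matters because the bootstrap and permutation machinery re-runs
  the estimator thousands of times.
* **Search interval and tolerances.** $\rho$ is maximized by Brent search
  on $[-1+10^{-4},\,1-10^{-4}]$ to an absolute tolerance of $10^{-6}$;
  rectangle probabilities are floored at $10^{-12}$ so tables with empty
  corners keep a finite likelihood. Perfectly concordant tables drive the
  likelihood to the boundary; the estimate is clamped there and flagged.
* **Bivariate-normal CDF.** Rectangle probabilities use Genz's hybrid
  Gauss–Legendre algorithm, implemented in compiled code; it is accurate
  to ~1e-15 (validated against an independent implementation in the test
  suite) and fast enough for the resampling loops.
* **Many-valued variables.** When a column has more than 15 distinct
  values (configurable), threshold estimation becomes unstable and the
  polychoric estimate is within a hair of the Pearson correlation of the
  codes anyway, so the pair falls back to Pearson with a logged notice.
* **PSD repair.** Pairwise-assembled matrices need not be positive
  semi-definite; since the graphical lasso requires a PSD input, negative
  eigenvalues are clipped at zero and the matrix rescaled to unit
  diagonal, with the repair logged.

## Regularized network estimation: glasso + EBIC

Edges of the GGM are partial correlations,
$\mathrm{pcor}_{ij} = -\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}$ for the
precision matrix $\Theta$. With 8 nodes there are 28 candidate edges, and
unregularized estimates are noisy; the graphical lasso maximizes

$$\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda\sum_{i\neq j}|\Theta_{ij}|$$

shrinking small edges exactly to zero. `select_network()` fits the path of
100 log-spaced $\lambda$ values between $\lambda_{\max}$ (the largest
absolute off-diagonal correlation, at which the network is empty) and
$\lambda_{\max}/100$, and selects the model minimizing the extended BIC

$$\mathrm{EBIC} = -n\,(\log\det\Theta - \mathrm{tr}(S\Theta)) + E\log n + 4E\gamma\log p,$$

with $\gamma = 0.5$ by default, the standard conservative choice for
psychological networks. Conventions fixed here (they must be, for
cross-implementation comparability): the likelihood term is scaled by $n$
(only within-path differences matter); edge presence means
$|\mathrm{pcor}| > 10^{-8}$ (solver zeros are exact, but the
symmetrization guard keeps a threshold); EBIC ties break toward larger
$\lambda$, i.e. the sparser model. The block-coordinate-descent solver is
validated in the tests against three independent oracles: direct matrix
inversion at $\lambda = 0$, the KKT optimality conditions at
$\lambda > 0$, and the diagonal solution at $\lambda \ge \lambda_{\max}$.

## Centrality

`centrality_table()` reports node strength
$s_i = \sum_{j \ne i} |w_{ij}|$, closeness and betweenness, raw and
z-standardized. The path-based indices follow the conventions of the
standard psychometrics toolchain: edge length is $1/|w_{ij}|$, shortest
paths by Dijkstra, betweenness with fractional credit across tied
shortest paths (validated against exhaustive path enumeration on small
networks), closeness as the reciprocal of summed distances restricted to
the node's component (isolated nodes get closeness 0, and the table is
flagged when any pair is unreachable). Only node strength is treated as
the headline index; the distance-based indices are computed and emitted
but are typically the first to lose stability.

# Accuracy and stability analyses

`edge_ci_bootstrap()` resamples subjects with replacement and re-runs the
entire pipeline per replicate, yielding 95% percentile CIs per edge
(percentile rather than BCa, matching common practice in this
literature). `difference_tests()` builds percentile CIs around
replicate-wise differences of two edges or two node strengths; a
difference is significant exactly when zero is outside its CI. These
within-network tests are deliberately *not* corrected for multiple
comparisons; the output says so.

`case_dropping_stability()` drops increasing proportions of cases,
re-estimates, and correlates subset centralities with the full-sample
ones. The CS-coefficient of an index is the largest drop proportion at
which that correlation is at least 0.7 with probability at least 0.95;
an index is "stable" when CS $\ge$ 0.5. Undefined correlations (zero
variance, e.g. an empty subset network) count against the criterion, as
do failed re-estimations. Subsets smaller than three times the node count
are skipped with a notice.

# Between-group comparison

`compare_networks()` is a two-group permutation test run over four
statistic families: network structure (maximum absolute edge difference),
global strength (absolute difference of summed absolute edge weights),
each individual edge, and each node strength. Each permutation
re-estimates both networks from a random regrouping of the pooled
subjects with the original group sizes, so the null distribution reflects
the entire estimation pipeline. p-values use the add-one formula
$(1 + \#\{T_{perm} \ge T_{obs}\})/(1 + B)$; two-sidedness is built into
the absolute-value statistics. Edge and strength families are
Holm-adjusted within family. With $m$ edges in a family, Holm
significance at level $\alpha$ is only attainable when the number of
permutations exceeds $m/\alpha - 1$; plan permutation counts accordingly
(the default 1000 is ample for 28 edges at $\alpha = 0.05$).

`compare_groups()` runs the battery for all pairs of group levels — a
six-group design yields 15 comparisons per family; there is deliberately
no joint k-group model. Because the literature is ambiguous about whether
Holm should be applied within each comparison or across the battery, both
are reported: `p_holm_within` (per family, per comparison) and
`p_holm_across` (per family, pooled over all pairwise comparisons).

# The synthetic-data generator

`build_precision()` + `sample_ordinal()` generate grouped ordinal data
from a known sparse GGM, which is what makes every downstream stage
testable against ground truth. Structures: chain, hub, random-sparse
(Bernoulli edges), or an explicit matrix. The precision matrix has unit
diagonal and $-r$ at structural edges, so present edges have partial
correlation exactly $r$ and absent edges exactly zero. When a requested
pattern/magnitude pair is jointly infeasible (indefinite), the matrix is
repaired by a diagonal shift followed by unit-diagonal rescaling —
equivalently a uniform shrink of all edges — iterated until the smallest
eigenvalue clears a 0.05 margin; the achieved magnitude is recorded and a
warning raised. Latent scores are multivariate normal with correlation
equal to the unit-diagonal-rescaled inverse precision, then thresholded.

Defaults emulate the motivating study design: eight nodes named after the
S-QoL18 dimensions, five response categories at equiprobable thresholds
(the instrument's exact item format is not public, so this is the neutral
choice, and both category count and thresholds are configurable), group
sizes freely configurable up to the cohort-scale 925/212/275/133/179/225
split used in the end-to-end tests, and per-group seed offsets so that
adding a group never perturbs earlier groups' draws. An optional affine
`score_mapping` writes 0–100 scores instead of category codes, mirroring
how such instruments are published.

What the generator does *not* emulate: item-level structure aggregated
into dimension scores, missing data (the reader applies listwise
deletion, the generator produces complete data), floor/ceiling-skewed
thresholds unless explicitly supplied, and any longitudinal dependence.
Passing tests therefore demonstrate correctness of the estimation
machinery under the latent-normal measurement model, not robustness to
violations of it.

# Numerical choices and degenerate inputs

* Constant columns are rejected as degenerate before estimation.
* A correlation matrix with all-zero off-diagonals short-circuits to the
  empty network (degenerate single-value path).
* Solver non-convergence marks a path entry unusable; selection runs over
  usable entries only, and an all-unusable path is a run-level error.
* Bootstrap/permutation replicates that fail to estimate are logged and
  excluded (permutations are re-drawn once first); failure rates above
  10% (bootstrap) or 5% (permutation) trigger warnings.
* All resampling is reproducible from the seed alone; the study driver
  derives stage seeds from one global seed and stamps every artifact
  with the configuration hash and seed.

# Problem sizes used in the validation suite

The test suite validates the pipeline at deliberately chosen scales:
polychoric recovery at $n = 5000$ (50 replicates), chain-structure
recovery at $n = 2000$ (20 replicates), permutation-test calibration with
200 simulated null studies of 100 permutations each, bootstrap difference
tests at $n = 2000$ with 250–500 replicates, case-dropping stability at
$n = 10{,}000$ with 100 subsets per proportion, and an end-to-end
six-group null study at the cohort's group sizes with 100 permutations.
These sizes give stable Monte Carlo estimates of each property while
keeping the full suite comfortably runnable on a laptop.

# Known limitations

* EBIC-glasso on polychoric input tends to admit a few small spurious
  edges at moderate-to-large $n$: in our chain-recovery simulations the
  true edges are essentially always found, but replicates frequently
  include several false edges with $|\mathrm{pcor}|$ in the 0.002–0.03
  range (the solver itself is verified against independent
  implementations, so this is a property of the selection criterion on
  discretized data, not a bug). Interpret very small edges with caution.
* The permutation comparison cannot model all six groups jointly; the
  battery of pairwise tests with Holm correction is the honest
  alternative, at some cost in power.
* Within-network difference tests are uncorrected by design and should
  be read as descriptive.
* The GGM is undirected; nothing here supports directional or
  longitudinal claims.
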