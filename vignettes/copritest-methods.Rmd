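---
title: "Methods: co-primary accuracy testing with multiple index tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-primary accuracy testing with multiple index tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copritest)
```

## Model and hypotheses

A diagnostic accuracy study observes, for each of $n = n_1 + n_0$
subjects, a reference-standard disease status $D_i \in \{0,1\}$ and $m$
binary index-test results $T_{ij}$. Test $j$ has sensitivity
$se_j = P(T_j = 1 \mid D = 1)$ and specificity
$sp_j = P(T_j = 0 \mid D = 0)$. Against minimal acceptance criteria
$(se_0, sp_0)$ the co-primary null hypothesis of test $j$ is

$$H_{0,j}: \; se_j \le se_0 \;\; \text{or} \;\; sp_j \le sp_0,$$

rejected by the intersection–union rule
$\varphi_j = 1 \iff Z_j = \min(Z_j^{se}, Z_j^{sp}) > c_\alpha$ with the
Wald statistics $Z_j^{se} = (\hat{se}_j - se_0)/\sqrt{\hat{se}_j(1 -
\hat{se}_j)/n_1}$ (analogously for specificity). Because *both* margins
must be rejected for one test, the pair of endpoints needs no
multiplicity adjustment of its own; only the $m$ tests do. This asymmetry
runs through the whole package: Bonferroni divides $\alpha$ by $m$ (not
$2m$), and comparison regions are wider than confidence regions by the
same factor.

### Estimation and shrinkage

Accuracy estimates add a pseudo-count $h$ to successes and failures:
$\hat{se}_j = (n_{j,11} + h)/(n_1 + 2h)$. The default $h = 0.5$ keeps
every estimate strictly inside $(0,1)$, so variance estimates never
degenerate when a test is perfect in a subgroup — a situation that is the
*rule* under least-favourable configurations, where one endpoint per test
has true parameter 1. The perturbation is $O(1/n)$ and vanishes
asymptotically; $h = 0$ recovers the ML proportions exactly and makes
`wald_statistics()` fail loudly on degenerate estimates. $h$ is exposed
everywhere (`shrinkage`) because no canonical value exists; 0.5 is the
symmetric Jeffreys-style choice.

### Binding endpoints

The endpoint attaining $\min(Z_j^{se}, Z_j^{sp})$ is called *binding*.
Exact ties are recorded as `se` — an arbitrary but deterministic
convention that only affects diagnostics and the maxT correlation matrix
on a measure-zero event.

## Multiple comparison procedures

* **none** — $c_\alpha = z_{1-\alpha}$. Controls each test's error, not
  the FWER; kept as the baseline the simulations quantify.
* **bonferroni** — $c_\alpha = z_{1-\alpha/m}$.
* **maxT** — $c_\alpha$ is the equicoordinate $(1-\alpha)$-quantile of an
  $m$-variate $N(0, \hat R)$. Under the least-favourable configuration
  (LFC) most compatible with the data, only the binding endpoint of each
  test sits at its boundary (the other parameter is 1 and its statistic
  diverges), so $Z_j$ reduces to the binding statistic and $\hat R$ is the
  empirical correlation of the binding correct-decision indicator columns:
  within the diseased subgroup for two `se`-binding tests, within the
  non-diseased subgroup for two `sp`-binding tests, and 0 across subgroups
  (independent samples). Whether the reference construction builds
  $\hat R$ from all $2m$ statistics or the $m$ binding ones is not
  published; the binding-endpoint reading is used because it is the one
  that makes the procedure an $m$-dimensional (not $2m$-dimensional)
  adjustment, consistent with the $\alpha/m$ comparison-region scaling.
* **pairs bootstrap** — whole subject rows are resampled with
  replacement, stratified by disease status so each replicate keeps
  exactly $n_1$ cases and $n_0$ controls (the fixed-size case-control
  design; stratification also rules out empty subgroups). Replicate
  statistics are centred at the original estimates and studentized with
  the replicate standard error; the critical value is the
  $\lceil (1-\alpha) B \rceil$-th order statistic of the replicate maxima.
* **wild bootstrap** — within-subgroup residuals of the correctness
  indicators are resampled and multiplied by one standard-normal weight
  per subject (shared across tests, preserving the between-test
  correlation). The perturbed values are not on the 0/1 scale of the
  data, so standard errors are taken from the original shrunk estimates
  rather than recomputed. For normal weights the implementation
  aggregates the weights landing on each source row into
  $\sqrt{N_r}\,z_r$ with multinomial $N$ — distributionally exact and
  vectorizable over all $B$ replicates.
* **mbeta** — two independent Bayesian models for the subgroups with
  conjugate $\text{Beta}(a + x, b + n - x)$ margins (default uniform
  prior). Simultaneous one-sided bounds come from a common quantile level
  $\gamma$, raised by bisection until the joint posterior probability
  that all *relevant* parameters exceed their $\gamma$-bounds drops to
  $1-\alpha$; with the default `lfc_pr = 1` the relevant parameter of each
  test is its binding endpoint (smaller posterior-median margin over the
  threshold). No adjusted p-values exist for this procedure.

### Why the bootstraps use the binding endpoint

A symmetric alternative — recording $\max_j \min(Z_j^{*se}, Z_j^{*sp})$
over *centred* replicate statistics — is degenerate: a test that is
perfect in one subgroup has a centred statistic identically zero there,
pinning the minimum at or below zero, and even for a single test with
interior parameters the minimum of two near-independent centred
statistics has a $97.5\%$ quantile near 1.0 rather than $z_{0.975}$.
The bootstraps therefore mirror the maxT construction exactly: they
approximate the null distribution of the maximum *binding* statistic
under the estimated LFC. With this reading all three adjusted procedures
agree at $m = 1$ with the unadjusted test, as they must.

### mbeta joint posterior: a documented approximation

The exact multivariate beta-binomial posterior is not reproduced; the
joint law is approximated by a Gaussian copula with conjugate Beta
margins and latent correlations equal to the empirical correlations of
the correctness indicators per subgroup. This matches the margins exactly
and the dependence to first order. Consequences are confined to the
simultaneity adjustment (the $\gamma$ search); the univariate margins and
the $m = 1$ case are exact up to Monte-Carlo error, which the test suite
verifies against the closed-form Beta quantile.

## Comparison vs. confidence regions

Both region types are one-sided rectangles
$(\hat{se}_j - c^* s_{j}^{se},\, 1] \times (\hat{sp}_j - c^* s_j^{sp},\, 1]$,
clamped below at 0, with containment in the open region of interest
$R = \{se > se_0 \wedge sp > sp_0\}$ read off with strict inequalities.
They differ only in $c^*$:

| procedure | comparison $c^*$ | confidence $c^*$ |
|---|---|---|
| none | $z_{1-\alpha}$ | $z_{1-\alpha/2}$ |
| bonferroni | $z_{1-\alpha/m}$ | $z_{1-\alpha/(2m)}$ |
| maxT | its $m$-dim critical value | equicoordinate quantile of the $2m$-dim block-diagonal correlation |
| bootstrap | its critical value | $(1-\alpha)$-quantile of the max over all $2m$ centred statistics |

Comparison-region containment is *algebraically identical* to
$Z_j > c_\alpha$, so region decisions and test decisions coincide exactly
(a property test asserts this across procedures). Confidence regions
cover all $2m$ parameters simultaneously and are strictly more
conservative; the bootstrap $2m$-recipe (max over all centred statistics)
is the natural extension since no explicit reference construction is
published.

## Synthetic data generators

### LFC setting

Correctness indicators $Q_{ijg} = 1(T_{ij} = D_i)$ are generated per
subgroup as dichotomized equicorrelated Gaussians. The latent correlation
is moment-matched (`binary_to_normal_correlation()`) by solving the
bivariate-normal rectangle probability — computed by adaptive 1-D
quadrature of the conditional normal CDF to $10^{-12}$, root-bracketed to
$10^{-8}$ — so the binary margins are exact and pairwise correlations hit
their targets (verified at $n = 10^5$ within 3 Monte-Carlo SEs). Per test
$j$, the vector $b$ selects which endpoint sits exactly at its boundary;
the other parameter is 1 and its column is constant, and degenerate
parameters are excluded from the correlation system. Defaults where no
canonical value exists, fixed once and documented: equicorrelation
$\rho = 0.5$ and alternating $b = (1,0,1,0,\dots)$, which balances the
two endpoints across tests.

### Biomarker setting

$l$ markers are multivariate binormal: $V \mid D=0 \sim N(0, R_0)$,
$V \mid D=1 \sim N(\mu_1, R_1)$ with unit variances, equicorrelated
$R_0 = R_1$, and $\mu_{k1} = \sqrt{2}\,\Phi^{-1}(AUC_k)$. Tests
dichotomize markers at cut points, $T_j = 1(V_{k_j} > c_j)$, with true
accuracies $se_j = \Phi(\mu_{k_j 1} - c_j)$, $sp_j = \Phi(c_j)$. Cut
points placed at quantiles of the *pooled* marker distribution use the
theoretical two-component-mixture quantiles
(`pooled_marker_quantiles()`), keeping the truth table identical across
replicates.

### What the generators do not emulate

Marker missingness, verification bias, imperfect reference standards,
clustered or paired-reader designs, and non-normal marker distributions
(a bi-exponential variant would stress the binormal-calibrated
procedures; a hook for alternative marker laws is left open). A green
simulation therefore establishes calibration *within* these models, not
robustness beyond them.

## Simulation engine

`run_scenario()` applies every requested procedure to the *same*
synthetic datasets. Replicate $r$ draws its dataset from seed
$\texttt{base\_seed} + r$; procedure-internal randomness uses the
disjoint stream $\texttt{base\_seed} + 10^6 + r + 3\cdot 10^7 k$ with $k$
the procedure's index in a canonical order, so adding or reordering
procedures never changes another procedure's draws. FWER is the fraction
of replicates with at least one rejection of a true null, disjunctive
power the fraction with at least one rejection of a false null; each is
reported with $\sqrt{p(1-p)/n_{sim}}$. In an LFC scenario every null is
true and power is reported `NA` (and vice versa when generating deep in
the alternative). Failed replicates are counted and surfaced per
procedure, never silently dropped. Power scenarios are expressed by
generating at one boundary and testing against lower thresholds — the
generator's truth table is reclassified against the analysis hypothesis.

## Numerical choices

* **Equicoordinate quantile.** The smallest $c$ with
  $P(\max_j X_j \le c) \ge 1-\alpha$ is taken directly as the
  $\lceil (1-\alpha) N \rceil$-th order statistic of a fixed-seed
  Monte-Carlo sample of the coordinate-wise maximum — equivalent to
  bisecting on randomized integration values but without the redundant
  outer loop, and deterministic given the seed. Default $N = 10^5$
  resolves the quantile to a few parts in a thousand; the simulation
  engine uses $N = 2\cdot 10^4$ per replicate, whose ~0.015 quantile
  noise is independent across replicates and negligible against the
  simulation's own Monte-Carlo error. A $10^6$-draw brute-force oracle
  pins the quantile within 0.01 in the test suite.
* **PSD repair.** Zero-filling cross-subgroup blocks can make a
  finite-sample correlation estimate indefinite; eigenvalues are clipped
  at $10^{-8}$ and the diagonal renormalized before Cholesky.
* **Bootstrap quantile.** The conservative order statistic
  $\lceil (1-\alpha) B\rceil$, not an interpolated quantile: it
  guarantees $\ge 1-\alpha$ coverage of the resampled distribution.
* **Adjusted p-values** are computed on the same Monte-Carlo/bootstrap
  sample as the critical value, making the duality
  $p_j \le \alpha \iff \varphi_j = 1$ exact for the parametric
  procedures and exact up to the $(B+1)$ add-one convention for the
  bootstraps.
* **Degenerate inputs.** Estimates exactly 0/1 with $h = 0$ raise an
  error naming the shrinkage remedy; constant indicator columns enter
  correlation matrices as 0 with a warning; infeasible binary
  correlations report the attainable range.

## Known limitations

* Wald-based bounds are liberal for proportions near 1 at small subgroup
  sizes; this is exactly the small-sample FWER inflation of the
  parametric procedures that the simulations quantify, and it also makes
  simultaneous confidence-region coverage dip a few points below nominal
  outside the moderate-proportion regime.
* The maxT quantile is Monte-Carlo based; results are reproducible via
  seeds but carry $O(10^{-3})$–$O(10^{-2})$ quantile noise depending on
  the draw count.
* The mbeta procedure's joint posterior is a copula approximation (see
  above), and its loss-function-based exact counterpart is out of scope.
* Contrast tests against a common comparator, non-inferiority margins,
  stepwise procedures, FDR control, two-sided hypotheses and more than
  two subpopulations are out of scope.
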