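---
title: "Models and methods behind exactNB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind exactNB}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exactNB)
```

# The error model

Read counts from a sequencing assay are modelled per gene $i$ and sample
$j$ as negative binomial,
$$K_{ij} \sim \mathrm{NB}(\mu_{ij}, \sigma^2_{ij}),$$
with two structural assumptions. First, the mean factorizes into a
per-sample *size factor* $s_j$ (sequencing depth) and a per-condition
expression strength $q_{i,\rho(j)}$, where $\rho(j)$ is the condition of
sample $j$:
$$\mu_{ij} = s_j\, q_{i,\rho(j)}.$$
Second, the variance decomposes into Poisson *shot noise* and a *raw
variance* term,
$$\sigma^2_{ij} = \mu_{ij} + s_j^2\, v_{\rho}(q_{i,\rho(j)}),$$
with the raw variance a smooth function of the expression strength. The
smoothness assumption is what makes the method work with two or three
replicates: thousands of genes at similar expression levels jointly
determine $v_\rho(q)$, where per-gene variance estimates alone would be
hopelessly noisy.

The decomposition follows from a hierarchical picture: the true fragment
concentration for gene $i$ in sample $j$ is a random variable $R_{ij}$
with mean $q_{i\rho}$ and variance $v_{i\rho}$ across replicates, and the
count is Poisson with rate $s_j r_{ij}$. By the law of total variance the
marginal variance is $\mu + s^2 v$; if $R_{ij}$ is gamma distributed, the
marginal is exactly negative binomial. The simulator
(`simulateCounts`) implements precisely this hierarchy, which is why it can
serve as the reference model for validating the pipeline.

Quantities divided by $s_j$ are said to be on the *common scale*.

# Size factors

`estimateSizeFactors` uses the median of ratios to a pseudo-reference
sample,
$$\hat s_j = \mathrm{median}_i \; \frac{k_{ij}}{(\prod_{v} k_{iv})^{1/m}},$$
the denominator being the geometric mean across samples. The median makes
the estimate insensitive to a minority of strongly differential genes,
which can dominate total-count ratios. Genes with a zero count in any
sample are excluded (their geometric mean is zero and the ratio
undefined); if no gene is everywhere positive the function asks the user
to supply factors manually (`sizeFactors<-` accepts externally computed
values, e.g. total-count ratios). No further normalization is applied: the
pseudo-reference construction is self-normalizing.

# Variance estimation

For each condition $\rho$ with $m_\rho \ge 2$ replicates,
`conditionMoments` computes per gene the common-scale mean
$\hat q_{i\rho}$, the common-scale sample variance $w_{i\rho}$, and the
expected shot-noise contribution
$$z_{i\rho} = \frac{\hat q_{i\rho}}{m_\rho} \sum_{j:\rho(j)=\rho}
\frac{1}{\hat s_j}.$$
The difference $w_{i\rho} - z_{i\rho}$ is an unbiased estimator of the raw
variance (the test suite verifies this by Monte-Carlo on 50,000 simulated
genes), but far too noisy at realistic replicate numbers to use per gene.
Instead `fitVarianceFunction` fits the conditional mean of $w$ given $q$
by local likelihood regression and sets
$$\hat v_\rho(q) = \max\bigl(0,\; w_\rho(q) - q \cdot
\textstyle\sum_j (1/\hat s_j)/m_\rho\bigr).$$
The clamp at zero keeps the negative binomial constraint
$\sigma^2 \ge \mu$; a clamped gene is effectively treated as Poisson.

## The local regression, concretely

Sample variances are sums of squares: their residuals around the
conditional mean are strongly right-skewed (for $m_\rho$ replicates,
$w/\mathbb{E}[w]$ is gamma with shape $(m_\rho-1)/2$), so least squares
would be badly miscalibrated. The fit is therefore a **gamma-family GLM
with log link**, fitted locally: at each of 200 knots equally spaced in
$\log q$ between the 0.1% and 99.9% quantiles of $\hat q$, a weighted IRLS
fit with tricube kernel weights and a nearest-neighbour bandwidth covering
70% of the points (both configurable). The local polynomial is
**quadratic in $\log q$** — the local-regression convention — which is
needed in practice: under the wide default bandwidth a local linear fit
cannot track the curvature where the variance crosses over from
shot-noise-dominated ($w \sim q$) to overdispersion-dominated
($w \sim \alpha q^2$) and overestimates the variance there by tens of
percent. With the quadratic fit, a constant squared coefficient of
variation (SCV) of 0.1 is recovered within about $\pm 15\%$ across the
central 90% of the mean range at $n = 10{,}000$ genes and $m_\rho = 2$
(the acceptance script reports the measured worst ratio).

Details and edge cases:

* Genes with $\hat q = 0$ carry no information and receive $\hat v = 0$;
  genes with $w = 0$ (identical replicate columns) are also excluded from
  the fit, because the gamma likelihood has no mass at zero.
* Between knots the fitted values are interpolated linearly in $\log q$.
* Outside the fitted domain the function is continued at the boundary
  knot's raw SCV with the shot-noise part re-added:
  $w(q) = q\,b + \mathrm{SCV}_b\, q^2$. This prevents negative or
  explosive extrapolation for extreme-count genes.
* If the IRLS does not converge at a knot, the fit falls back to weighted
  least squares of $\log w$ on the same design with a half-residual-variance
  back-transform correction, and says so in a message.
* A minimum of 50 usable genes (configurable) is required.

`fitDiagnostics` referees the fit: per gene, the ratio $w_i /
w(\hat q_i)$ is referred to the gamma distribution with shape
$(m_\rho-1)/2$ and mean 1; well-calibrated fits give approximately uniform
quantiles. This is an analog of a residual Q–Q plot adapted to the skewed
null; the tests verify near-uniformity (Kolmogorov–Smirnov distance
< 0.02 at $n = 10{,}000$) when the data come from the fitted model, and a
clear signal (KS > 0.2 at $m_\rho = 4$) when the fit is off by a factor of
two. At $m_\rho = 2$ the same factor-two misfit yields a theoretical KS
distance of only 0.166 — a reminder of how little information two
replicates carry about a variance.

## Designs without replication

`estimateVarianceFunctions` supports four sharing modes:

* `per-condition` — one fit per condition from its own replicates (the
  default; requires $m_\rho \ge 2$ everywhere);
* `pooled` / `shared-from-replicated` — one fit from the $(\hat q, w)$
  points of all replicated conditions, assigned to every condition,
  including unreplicated ones: the assumption is that the variance–mean
  dependence of the replicated condition holds for the unreplicated one;
* `blind` — all samples treated as replicates of a single condition. This
  works even for a 1-versus-1 design under the assumption that most genes
  are not differential; truly differential genes act as outliers that
  inflate the fit somewhat (the gamma family's heavy right tail limits
  their leverage), so the resulting test is conservative. The test suite
  quantifies this inflation on simulated data.

Each condition always keeps its **own** shot-noise coefficient
$\sum_j (1/\hat s_j)/m_\rho$, whatever fit it shares.

# The exact test

To compare conditions $A$ and $B$ the test conditions on the total count.
Per gene, with condition sums $k_{iA}, k_{iB}$ and $k_{iS} = k_{iA} +
k_{iB}$,
$$p_i = \frac{\sum_{a+b=k_{iS},\; p(a,b)\le p(k_{iA},k_{iB})} p(a,b)}
{\sum_{a+b=k_{iS}} p(a,b)},$$
where $p(a,b) = \Pr(K_{iA}=a)\Pr(K_{iB}=b)$ under the null
$q_{iA} = q_{iB}$. Each condition sum is itself a sum of NB variables and
is approximated by a single NB with moments
$$\hat\mu_{iA} = \sum_{j\in A} \hat s_j\, \hat q_{i0}, \qquad
\hat\sigma^2_{iA} = \sum_{j\in A} \hat s_j\, \hat q_{i0} +
\hat s_j^2\, \hat v_A(\hat q_{i0}),$$
evaluated at the pooled mean $\hat q_{i0}$.

Choices a user should know about:

* **The pooled mean is a per-sample average.** $\hat q_{i0}$ is the sum of
  common-scale counts over both conditions' samples **divided by
  $m_A + m_B$**. Only with this convention are the summed-moment formulas
  above dimensionally consistent (they multiply $\hat q_{i0}$ back by each
  sample's $\hat s_j$ and sum over samples).
* **Moment matching.** NB parameters are derived from $(\mu, \sigma^2)$ by
  plain moment matching, $r = \mu^2/(\sigma^2-\mu)$, isolated in the
  `nbParams` constructor so an alternative (e.g. bias-corrected)
  parameterization could be swapped in. When $\sigma^2 \le \mu$ the
  Poisson limit is used; $\mu = 0$ degenerates to a point mass at zero
  (such genes get $p = 1$ and stay in the BH denominator).
* **Evaluation of the sums.** All arithmetic is in log space. For
  $k_S \le 10{,}000$ every split is enumerated; beyond that, only the
  contiguous window where $\log p(a,b)$ is within $36\ln 10$ of its
  maximum contributes (terms below $10^{-36}$ relative are dropped — far
  below reporting precision), found by grid search plus binary search on
  the log-concave profile. The observed split is always included. Within
  the window the log pmfs are computed by a single anchored evaluation and
  a cumulative sum of log probability ratios. The test suite checks
  agreement with literal enumeration to $10^{-12}$ for all totals up to
  200 and at totals near $4\times 10^4$.
* **Ties.** The comparison $p(a,b) \le p(k_{iA},k_{iB})$ uses a relative
  tolerance of $10^{-8}$ on log probabilities so that exact ties are not
  lost to floating-point noise.
* **Fold changes** are ratios of per-condition common-scale means; $x/0$
  is reported as infinite, $0/0$ as undefined (`NA`).
* Benjamini–Hochberg adjustment is applied over all genes with defined
  p-values (via `stats::p.adjust`); the conventional reporting threshold
  is an FDR of 10%.

Because the counts are discrete, p-values are super-uniform (conservative)
rather than exactly uniform, with a visible point mass at $p = 1$ for low
counts. The Poisson $\chi^2$ test (`poissonChisqPvalues`) is included as a
comparator only: on overdispersed data it is grossly anti-conservative
(fraction of $p \le 0.05$ around 0.6 on the null simulations the
acceptance script runs), which is the central argument for modelling the
raw variance at all.

# Variance-stabilizing transformation

Given the fitted variance–mean relation, the transformation
$$\tau(\kappa) = \int_0^{\kappa} \frac{dq}{\sqrt{w(q)}}$$
makes the variance of transformed common-scale counts approximately
independent of the mean, which is what distance-based methods
(clustering, classification) implicitly assume. Choices:

* The integrand uses the **full** common-scale variance at a reference
  size factor of one, $w(q) = q + \hat v(q)$: shot noise included. A
  per-sample-exact transform is impossible with a single $\tau$, and the
  inclusion gives the correct Poisson limit $\tau = 2\sqrt{\kappa}$.
* The integral is computed after the substitution $u = \sqrt{q}$, which
  removes the integrable $1/\sqrt{q}$ singularity at zero (the integrand
  tends to a finite limit where $w \sim cq$), with composite Simpson on
  20,000 knots log-spaced in $\kappa$; $\tau$ is stored against $u$ so
  linear interpolation is exact in the Poisson limit. Evaluation beyond
  the precomputed range extends the integral on demand.
* $\tau$ is anchored at $\tau(0) = 0$; the constant of integration is
  otherwise arbitrary, and a fixed anchor makes outputs reproducible. For
  a purely quadratic variance law (no shot-noise part) the integral
  diverges at zero; differences $\tau(\kappa) - \tau(\kappa')$ remain
  correct, matching $\ln\kappa / \sqrt{\alpha}$ to $10^{-6}$.

`sampleDistances` then gives the Euclidean distance matrix between
transformed sample columns; dendrogram construction is left to standard
tooling (`hclust`, `pheatmap`).

# The simulator and what the tests do and do not show

`simulateCounts` draws from the gamma-Poisson hierarchy with defaults
chosen to emulate a bulk RNA-Seq experiment: per-gene means log-uniform on
$[0.1, 10^5]$ (spanning the dynamic range of typical libraries), unit
size factors, constant raw SCV $v(q) = 0.1\,q^2$ (biological replicates of
the same condition typically scatter with a coefficient of variation of a
few tens of percent), no differential genes. Differential genes, when
requested, get log2 fold changes uniform in $[1, 3]$ with random sign —
large enough to be detectable at moderate counts, small enough not to be
trivial. The gamma rate distribution is parameterized as shape $q^2/v$,
scale $v/q$ and degenerates to a point mass when $v = 0$. A fixed seed
makes the output bit-for-bit reproducible.

The harnesses `type1ErrorExperiment` and `powerExperiment` run the entire
pipeline (size factors estimated, variance fitted, exact test) on such
data. The standard problem sizes used by the test suite and the acceptance
script — 10,000 genes with 2+2 samples for type-I error and SCV recovery,
50,000 single-condition genes for the unbiasedness check, 4,000 genes for
the power structure — are large enough that Monte-Carlo error is small
against the tolerances checked, and the runs complete in about a minute
each.

What passing these checks shows: the implementation is internally
consistent with its own error model, controls type-I error under that
model where a Poisson test does not, and recovers known variance
structure. What it does not show: real libraries violate the model in ways
the simulator deliberately omits — GC and length biases, correlated genes,
outlier samples, raw SCV that falls with the mean rather than staying
constant, and batch effects. The variance-function form is data-driven, so
the mean-dependence of the SCV is handled, but the per-gene independence
and gamma rate assumptions are idealizations; results on real data should
always be sanity-checked with `fitDiagnostics` and the VST-based sample
distances.

# Known limitations

* Only two-condition contrasts; multi-condition designs require pairwise
  contrasts chosen by the user. No covariates or GLM designs.
* No per-gene (empirical-Bayes) dispersion moderation: the raw variance is
  taken from the fitted smooth function alone. Genes whose true
  variability deviates strongly from the trend for their expression level
  are accordingly over- or under-called.
* The NB approximation to a sum of NB variables is a moment-matched
  surrogate, not exact; with very unequal size factors within a condition
  its accuracy degrades.
* Exact numerical agreement with other local-regression implementations is
  not guaranteed: bandwidth, knot grid and interpolation are stated above
  but are genuine choices, and different choices shift fitted variances by
  a few percent.
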