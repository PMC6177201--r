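---
title: "Subclass-driven inflation of cross-validated accuracy: model, theory and testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subclass-driven inflation of cross-validated accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The multilevel model

`nestedmvpa` works with two-class trial data in which each trial belongs to
a *subclass* that is nested within its class: a repeated stimulus, a
subject, a session, a recording block. The generative model behind both the
simulator and the analytic results is

$$ y_{ijk} = C_i + S_{ij} + \epsilon_{ijk}, $$

where $C_i$ ($i \in \{1,2\}$) is the class centroid, $S_{ij}$ the offset of
subclass $j$ from its class centroid, and $\epsilon_{ijk}$ trial noise. All
three components are isotropic Gaussians in $d$ dimensions with
per-dimension standard deviations $\sigma_C$, $\sigma_S$, $\sigma_W$. The
design is balanced: $K$ subclasses per class, $N$ trials per subclass. The
intraclass correlation
$ICC = \sigma_S^2 / (\sigma_S^2 + \sigma_W^2)$
measures how much of the class-unrelated variance is subclass-driven.

`generate_dataset()` draws all three components afresh for every dataset —
class centroids included, so `sigma_C` acts as a variance component exactly
like `sigma_S`, and `sigma_C = 0` yields identical class centroids. Draws
are consumed in a fixed documented order (class centroids, subclass
centroids class by class, trial noise class by class), which makes seeds
portable across platforms. A design with two nested subclass levels
collapses exactly onto this model because Gaussian variances add;
`collapse_levels()` returns the collapsed $\sigma_S$.

What the generator deliberately does **not** emulate: non-Gaussian or
anisotropic noise, temporal autocorrelation between trials, crossed (shared
across classes) subclass designs, and unbalanced designs. Passing tests on
this generator therefore demonstrates correctness of the machinery and of
the variance-component story, not robustness to every real-data pathology;
on real data the subclass labels must be known and the design balanced for
the block permutation test to be valid.

## Classifiers and cross-validation

Two linear classifiers are provided. The *mean-difference rule*
(`fit_mean_diff_lda()`) projects a test point onto the axis defined by the
difference of the empirical class means and thresholds at the midpoint
$\theta = (\bar\mu + \bar\nu)/2$; this is the classifier the chance-level
theory describes exactly. Points landing exactly on $\theta$ go to class 1 —
a measure-zero event for continuous data, pinned down only so that the
behaviour on constructed inputs is defined. The *linear SVM*
(`fit_linear_svm()`, via `e1071`, cost 1 by default, no feature scaling) is
the practitioner's workhorse; on the simulated designs its mean CCRs track
the mean-difference rule within a few percentage points, which the test
suite checks.

`cross_validate()` pools correct test classifications over folds (rather
than averaging per-fold rates), so unequal fold sizes cannot distort the
CCR; with stratified folds the two conventions coincide. Two fold schemes
matter:

* **Stratified trial-wise k-fold** (default $k = 2$, split-half): folds are
  stratified by class only. Members of one subclass generally appear in
  both training and test folds — deliberately so, because that transfer is
  the mechanism of the inflation under study.
* **Leave-one-subclass-out**: each fold holds out one whole subclass per
  class. No subclass structure can transfer from training to test, so the
  expected CCR at zero class effect is 50% regardless of $\sigma_S$ (tested
  to Monte-Carlo precision). Note that a trial-wise permutation test is
  still miscalibrated for this scheme's *null distribution spread*; holding
  subclasses together during permutation remains the safe default.

## Why accuracy is inflated, exactly

Project everything onto the discriminant axis and consider zero class
effect. The threshold is built from empirical class means that *contain*
the test trial's own subclass mean: writing $A$ for the signed distance of
a test trial from the threshold and $B$ for the class-mean difference, the
correct-classification event is $AB > 0$, and $A$ and $B$ are correlated
because the test subclass contributes $1/K$ of its class mean. For
mean-zero Gaussians $P(AB > 0) = \tfrac12 + \arcsin(\mathrm{corr})/\pi$,
and working out the variance components gives the closed form implemented
in `expected_ccr_closed_form()`:

$$ CCR(K, ICC) = \tfrac12 + \tfrac{1}{\pi}\arctan\lambda
   = 1 - \tfrac{1}{\pi}\arctan\sqrt{2\left(\tfrac{K}{ICC}-1\right)},
   \qquad \lambda^2 = \frac{ICC}{2(K - ICC)}. $$

It is exactly $1/2$ at $ICC = 0$, strictly increasing in $ICC$, strictly
decreasing in $K$: more subclass variance inflates more, more subclasses
dilute each subclass's $1/K$ leverage on the class mean. Even $ICC = 0.1$
with $K = 2$ shifts the chance level by about 5 percentage points.

With a class-mean separation $\delta$ along the axis, conditioning on the
class-mean difference reduces the expected CCR to a one-dimensional
integral,

$$ CCR = \int_{-\infty}^{\infty} \phi(q)\,
   \Phi\!\left(\frac{|\delta + q\,\sigma\sqrt{2\,ICC/K}|}
   {2\sigma\sqrt{1 - ICC/K}}\right) dq, $$

implemented in `expected_ccr_integral()` by adaptive quadrature with
absolute tolerance $10^{-10}$ per piece. The integration range is split at
the kink of the absolute value *and* at $q = 0$; without the second break a
kink far in the tail leaves a semi-infinite piece whose mass the adaptive
rule can miss entirely. $ICC = 0$ is special-cased analytically as
$\Phi(|\delta|/2\sigma)$ (the class-mean difference is then noiseless under
the model), avoiding a $0/0$ at the boundary. At $\delta = 0$ the integral
reproduces the closed form to $10^{-6}$; as $\delta/\sigma \to \infty$ it
tends to 1.

### The Monte-Carlo oracle

`mc_ccr_oracle()` validates both expressions by simulation that is faithful
to the regime the theory describes, and is kept independent of them: per
repetition it draws $K$ subclass centroids per class around fixed class
means $\pm\delta/2$, estimates the mean-difference rule from $N$ training
trials per subclass, and classifies $N$ *fresh* trials drawn around the
same subclass centroids. There is intentionally no cross-validation split:
the theory models the regime in which tested trials share their subclasses
with the training data, which is precisely the leakage that creates the
inflation. Defaults are $d = 1$ (the projected model is one-dimensional)
and $N = 100$; large $N$ matches the theory's assumption that empirical
subclass means are well estimated — at small $N$ the estimation noise
$\sigma_W^2/N$ acts as extra subclass variance and the simulated CCR sits
slightly above the formula. The test suite checks the full consistency
triangle (closed form = quadrature to $10^{-6}$; both within
$\max(2\,\mathrm{pp}, 3\,\mathrm{SE})$ of the oracle at 2000 repetitions
per cell) on a $K \in \{2,4,8\} \times ICC \in \{0.1,\dots,0.7\}$ grid.

In higher dimension the finite-sample inflation *exceeds* the asymptotic
closed form, because the subclass-driven separation accumulates over
dimensions in the estimated discriminant axis; the CCR-surface experiments
quantify this ($d = 100$ surfaces lie above $d = 10$ at matched settings).

## Permutation testing

**Balanced block permutation.** To remove class information while keeping
subclass structure intact, whole subclasses are reassigned: each of the two
new classes receives exactly $K/2$ subclasses from each original class.
There are $\binom{K}{K/2}^2/2$ distinct reassignments, the $1/2$ because
swapping the two new labels changes nothing. The enumeration realises this
factor constructively: new class 1 is required to contain the first
subclass of original class A. $K$ must be even and equal across classes;
unequal designs are rejected (they bias the test). $K = 6$ is the smallest
design with more than 100 permutations, i.e. the smallest that can resolve
p-values near 0.01; below that, the group-level null (`group_null()`)
aggregates evidence across subjects by repeatedly averaging one sampled
permutation CCR per subject.

Design choices made here, where more than one convention is defensible:

* If the total count is at most `n_perm`, the null is exhaustive; otherwise
  assignments are drawn uniformly **without replacement**, by sampling ranks
  and combinatorially unranking the two half-subsets, so even astronomically
  large designs need no explicit enumeration.
* The observed (identity) labelling is not itself a balanced assignment and
  never enters the null; its CCR is the test statistic.
* P-values use the add-one estimator
  $p = (1 + \#\{CCR_0 \ge CCR_{obs}\})/(1 + n)$ for sampled nulls (never
  zero, valid under exchangeability); exhaustive nulls use the plain
  proportion floored at $1/n$, counting the observed arrangement as one
  attainable outcome.
* Every permutation draw gets a fresh fold split, seeded from the scheme
  seed, so fold-split artefacts cannot correlate across draws; the
  alternative (one fixed split) would entangle the null with one particular
  partition.

**Trial-wise permutation** shuffles class labels over trials, destroying
class *and* subclass structure; its null is centred at 50% regardless of
$\sigma_S$, which is exactly why it is anticonservative for nested data.
It is provided both as the conventional baseline and for the
significance-bias experiments.

## The simulation experiments

`run_ccr_surface()`, `run_theory_validation()` and
`run_significance_bias()` reproduce the three study designs at configurable
scale: CCR surfaces over a $(\sigma_C, \sigma_S)$ grid (reference design:
$\sigma_W = 1$, grid $0\ldots0.6$, $d \in \{10, 100\}$, $K \in \{2, 10\}$,
120 trials per class), theory-versus-simulation tables, and
significance-bias maps $SB = P_{\sigma_S \ne 0} - P_{\sigma_S = 0}$, where
$P$ is the proportion of significant results and the reference is the
matched $\sigma_C$ cell without subclass variance (so $SB \equiv 0$ on the
$\sigma_S = 0$ column by construction).

Significance-bias nulls come in two modes. `per_dataset` (default) builds a
permutation null from each simulated dataset — the procedure available on
real data. `population` pools observed CCRs of reference datasets simulated
under the scheme's null condition (no effects at all for trial-wise; no
class effect but matched subclass variance for block-wise), which is the
population-level construction of the bias maps and an order of magnitude
cheaper. Both are exposed because they answer slightly different questions;
the package defaults to the one a practitioner can actually run.

Default scales are desk-sized and chosen so that all documented trends are
resolvable within Monte-Carlo error: 500 repetitions per surface cell, 2000
per theory cell, 200 datasets with 99 permutations each for the
permutation-contrast checks (at $\alpha = 0.05$ and 99 draws the add-one
p-value rejects exactly when at most 4 null draws reach the observed CCR,
an attainable level of exactly 0.05). Repetition counts are parameters
throughout; raising them tightens every binomial interval at linear cost.

## Limitations

* The theory covers the mean-difference discriminant; the SVM tracks it
  closely on these designs but has no closed form here.
* Balanced designs only: equal $K$ per class, equal $N$ per subclass, even
  $K$ for permutation. Unbalanced data must be subsampled or handled at the
  group level.
* Subclass labels must be known a priori; discovering latent subclasses is
  out of scope.
* Multi-class problems are not implemented; the binary results extend
  conceptually to one-vs-one/one-vs-all schemes but are not automated here.
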