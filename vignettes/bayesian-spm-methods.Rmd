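---
title: "Bayesian and classical statistical parametric mapping for 1D trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian and classical statistical parametric mapping for 1D trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bspm1d)
```

## The problem

Biomechanical experiments routinely produce *registered one-dimensional
continua*: a knee flexion angle, a plantar pressure, an EMG envelope,
sampled at (typically) 101 nodes spanning 0–100% of a movement cycle.
Testing hypotheses about such curves node by node inflates the Type I
error; collapsing each curve to a scalar discards the time course and
invites post-hoc region picking. Statistical parametric mapping (SPM)
keeps the whole continuum: a test statistic is computed at every node and
inference is carried out on the resulting *field*, with the multiple
comparison problem handled through the field's smoothness.

`bspm1d` implements two complementary inferential routes over the same
t-statistic field:

* **Classical SPM{t}** — random field theory (RFT) supplies a field-wide
  critical threshold and cluster-extent p-values. This answers
  *P(data at least this extreme | H0)* and can only ever reject the null.
* **Bayesian SPM** — a pointwise default-prior Bayes factor converted to a
  posterior probability map (PPM), thresholded directly or through
  q-values for FDR control. This answers *P(H | data)* at every node and
  can quantify evidence **for** a null — e.g. for left–right gait
  symmetry — which no p-value can.

## The Bayesian model

At each node the data enter only through the t statistic, its degrees of
freedom $\nu$ and the effective sample size $n$ ($n$ trials for a paired
design; $n_1 n_2 / (n_1 + n_2)$ with $\nu = n_1 + n_2 - 2$ for two
samples). Hypotheses are placed on the standardized effect size
$\delta = (\mu_1 - \mu_2)/\sigma$ with the JZS (Jeffreys–Zellner–Siow)
default prior: $\delta \sim \mathrm{Cauchy}(0, r)$, Jeffreys prior on the
variance. The scale presets are `medium` ($\sqrt2/2$), `wide` (1) and
`ultrawide` ($\sqrt2$); half of the prior mass lies within $\pm r$. This
default has the properties one wants of an omnibus screen: invariance to
measurement units, consistency as $n \to \infty$, and
$BF_{10} \to \infty$ as $|t| \to \infty$.

Two null hypotheses are supported:

* **point null** $H_0: \delta = 0$ against
  $H_1: \delta \sim \mathrm{Cauchy}(0, r)$, computed by adaptive
  quadrature of the JZS mixing-variance integral;
* **interval null** $H_0: |\delta| \le c$ against
  $H_1: |\delta| > c$, both obtained by truncating the *same* parent
  Cauchy$(0, r)$ to complementary regions. The Bayes factor is the ratio
  of posterior to prior odds of the two regions under the unconstrained
  model. The default $c = 0.2$ treats effects below Cohen's small-effect
  bound as practically null — appropriate for trajectory data, where
  registration error and natural variability make an exact point null
  implausible from the outset.

With prior odds $\pi = P(H_1)/P(H_0)$ (default 1),
$PP(H_1) = BF_{10}\pi / (1 + BF_{10}\pi)$ and $PP(H_0) = 1 - PP(H_1)$.
A $BF_{10}$ of 5 therefore means $P(H_1 \mid \text{data}) = 5/6$.

### From the map to clusters: PEP and q-values

The posterior error probability of claiming a hypothesis at a node is
$PEP = 1 - PP$. Two thresholding rules report supra-threshold clusters:

* conservative: $PP \ge 0.95$ nodewise;
* FDR-style: the **q-value** — the cumulative mean of the PEPs sorted
  ascending, mapped back to node order — kept at $q \le 0.05$. The first
  node admitted still needs $PP \ge 0.95$, but strongly correlated
  neighbours with slightly lower PP may join the same cluster, so
  q-clusters always *contain* the conservative clusters (a property the
  test suite checks over random maps). q-values are computed per
  hypothesis (from $PEP_{H1}$ and $PEP_{H0}$ separately), ties share the
  cumulative mean at their last tied rank, and no further monotonicity
  adjustment is applied beyond the defining cumulative mean.

## Classical RFT inference

The same t field is thresholded at the smallest $u$ for which the
expected-Euler-characteristic approximation

$$P\!\left(\max_q T(q) \ge u\right) \approx
  P(T_\nu \ge u) + R\,\frac{\sqrt{4\ln 2}}{2\pi}
  \left(1 + \frac{u^2}{\nu}\right)^{-(\nu-1)/2}$$

equals $\alpha/2$ per tail (two-tailed inference on $|t|$), where
$R = (Q-1)/\mathrm{FWHM}$ is the resel count. Smoothness is estimated
from the residual fields: residuals are scaled to unit norm per node,
differentiated along the node axis (central differences inside,
one-sided at the ends), and
$\widehat{\mathrm{FWHM}} = \sqrt{4\ln 2 / \overline{g^2}}$. Each
supra-threshold run receives a cluster-extent p-value from the standard
Poisson-clumping form
$p = 1 - \exp\{-E[m]\,e^{-\lambda k}\}$, with $E[m]$ the expected cluster
count at $u$ and $\lambda$ matched to the expected supra-threshold
measure; p-values are doubled for two-tailedness. Cluster extents are
counted in whole nodes and converted to resels — no sub-node
interpolation is performed, so third-decimal differences from
implementations that interpolate are expected; cluster *endpoints* are
unaffected. Degrees of freedom are classical (no smoothness-based
correction), and no special handling is given to clusters touching the
field ends.

## Numerical choices

* **Point-null quadrature.** The Cauchy prior is expanded as an
  inverse-gamma scale mixture of normals and the mixing variance is
  integrated by adaptive quadrature after the two-stage substitution
  $g = r^2 s$, $s = w/(1-w)$, which maps the domain to $(0,1)$ and keeps
  the integrand well conditioned down to the degenerate $r \to 0$ limit
  (where $BF_{10} \to 1$ exactly). All work is done in log space;
  $\log BF$ is capped at $\pm 700$ with a `capped` flag.
* **Interval-null region masses.** Marginal likelihoods over
  $[-c, c]$ and its complement are integrated over $\delta$ with
  breakpoints geometrically spaced around the sample effect estimate, so
  each segment has moderate dynamic range even when the region boundary
  cuts through the likelihood spike; far Cauchy tails are integrated
  separately. A dense-trapezoid fallback covers the rare segment the
  adaptive routine rejects. Agreement with an independent dense-grid
  Riemann oracle is checked to better than $10^{-5}$ relative error over
  random configurations in the test suite.
* **Posterior density grid.** `delta_posterior()` evaluates the
  normalized posterior of $\delta$ on a symmetric grid centred on
  $\hat d = t/\sqrt n$ with half-width $r \cdot \max(10, 10|t|/\sqrt n)$
  (20001 points), bounding the truncated tail mass below $10^{-8}$ for
  any realistic input.
* **Noncentral-t density.** `stats::dt(ncp = )` is exact but becomes slow
  (and warns) deep in its tails; evaluations are reflected onto the
  non-negative noncentrality side, and once the statistic sits below
  $e^{-18}$ central-t density — where the Bayes factor is decisively
  large regardless — a Laplace approximation of the defining
  scale-mixture integral replaces the whole call, keeping within-call
  ratios smooth. This approximation is never active in the regime the
  oracle comparisons probe.
* **Degenerate inputs.** A node with zero residual variance is reported
  as an error naming the node; all-zero residual matrices are rejected;
  a vanishing residual gradient returns the configurable FWHM cap
  (default $10Q$).

## The simulators, and what they do (not) show

`smooth_gaussian_fields()` convolves white Gaussian noise with a Gaussian
kernel of given FWHM, truncated at $4\sigma$, with every kernel column
rescaled to unit norm so each node — including the field ends — has unit
variance ("smooth unit Gaussian" is interpreted as unit *post-smoothing*
pointwise variance). `make_two_local_max()` adds Gaussian-pulse mean
bursts at 25% and 75% of the cycle to one of two groups of six trials;
the default pulse (amplitude 2.8 noise-SD units, FWHM 10 nodes) is
tuning, calibrated once so the classical SPM detects clusters near both
bursts in a majority of seeds at this small sample size.
`make_gait_like()` produces a knee-flexion-like baseline (stance bump
≈18° at 15%, swing peak ≈62° at 72% of the cycle) for two "legs", an
optional Gaussian-pulse asymmetry late in the cycle, and smooth trial
noise with a default within-subject SD of 2.5° — a realistic
cycle-to-cycle variability for treadmill walking. With a 2° minimal
relevant asymmetry this places the 80%-power sample size in the tens of
gait cycles.

These generators emulate registered, stationary, Gaussian, equal-variance
trajectories. Real movement data are none of these exactly: smoothness
varies along the cycle, amplitudes drift, and registration itself is
imperfect. Passing the calibration tests therefore demonstrates internal
consistency of the machinery under its own assumptions — not that the 5%
error rate or the power curve transfer verbatim to any particular
laboratory dataset.

`continuum_power()` estimates *omnibus* power — the probability that the
classical paired SPM rejects anywhere along the continuum — by
simulation from a null and an alternative continuum model (mean curve,
effect pulse, smooth noise). With the alternative equal to the null the
curve estimates the field-wide false positive rate, which the tests
require to sit within Monte-Carlo error of $\alpha$.

## Problem sizes used by the validation suite

The suite exercises the documented claims at sizes chosen to keep the
Monte-Carlo error meaningfully small: 20 + 20 random configurations for
the Bayes-factor oracles, 100 random maps for cluster nesting, 2000
replicates for the RFT error-rate calibration (binomial SD ≈ 0.5
percentage points), 100 seeds for smoothness recovery, 1000 iterations
for the null power calibration and a 3 × 3 grid at 200 iterations for
power monotonicity. `scripts/acceptance.R` recomputes the same
quantities from scratch under a caller-supplied seed.

## Design choices that were genuinely open

* **Effective sample size.** The two-sample Bayes factor uses
  $n_1 n_2/(n_1+n_2)$ with $\nu = n_1+n_2-2$, the standard JZS
  convention.
* **Prior odds.** Default 1 throughout; any other value propagates
  through `bf_to_posterior()` but none of the reported analyses use one.
* **One-sided alternatives** truncate the Cauchy prior to a half-line and
  are available for the point null; the interval null is two-sided by
  construction.
* **q-value scope.** q is computed per hypothesis, matching the two
  separate q columns a practitioner reports; pooling PEPs across both
  hypotheses simultaneously would mix discovery sets with different
  claims.
* **Node reporting.** Internally 0-based offsets never surface: all
  tables report 1-based inclusive node ranges plus percent of movement
  time, $100(q-1)/(Q-1)$.

## Known limitations

Only paired and two-sample t designs are covered (no ANOVA or
regression maps); priors are independent across nodes — the temporal
correlation that RFT exploits classically is used by the Bayesian route
only indirectly, through the q-value's cumulative averaging; smoothness
is assumed stationary along the field; and the two-sample test assumes
equal variances. Hierarchical priors, spatiotemporally correlated priors
and sequential sampling designs are natural extensions and are out of
scope here.
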