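---
title: "Testing topological features against the universal null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing topological features against the universal null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdanull)
```

## The model

A point cloud $X_n$ in $\mathbb{R}^d$ is turned into a filtration of
simplicial complexes — Vietoris–Rips (simplices are sets of points pairwise
within the scale) or Čech (sets of points whose balls at the scale have a
common point) — and its degree-$k$ persistence diagram records a
(birth, death) radius pair per $k$-cycle. Everything in this package is on
the **radius scale**: an edge enters either filtration at half the pairwise
distance, and a Čech simplex at its minimum-enclosing-ball radius. Since the
statistic below is provably insensitive to power transformations of the
persistence ratio, this convention affects reported ratios but none of the
inferences.

For a feature $p$ with $0 < b < d < \infty$ define the persistence ratio
$\pi(p) = d/b$ (scale-invariant, robust to outliers — an outlier-generated
cycle has a large lifetime $d-b$ but a modest ratio) and transform

$$\ell(p) = A \log\log \pi(p) + B, \qquad
A = \begin{cases}1 & \text{Rips}\\ 1/2 & \text{Čech}\end{cases}, \qquad
B = -\lambda - A \bar L,$$

with $\bar L$ the diagram mean of $\log\log\pi$ and $\lambda =
0.5772156649\ldots$ the Euler–Mascheroni constant (hard-coded to 20 digits;
never recomputed). The empirical claim the package operationalises is that
for noise features the $\ell$-values follow the parameter-free
**left-skewed Gumbel law** $F(x) = 1 - e^{-e^x}$, whose mean is $-\lambda$,
independently of the sampled space, the generating distribution, $d$, the
filtration, and $k$. All model dependence is absorbed by the single
intercept $B$, which is estimated from the diagram under test. Signal
contamination of $\bar L$ is benign: a handful of signal features among
hundreds of noise features moves a mean of $\log\log\pi$ values only
marginally, and an option to inject a known $B$ exists for simulation
studies.

Two algebraic identities are worth keeping in mind, because the test suite
leans on them:

* **Centring**: $\operatorname{mean}(\ell) = -\lambda$ exactly, for any
  nonempty diagram — a direct consequence of the definition of $B$.
* **Power invariance**: replacing every $\pi$ by $\pi^c$ ($c>0$) shifts
  $\log\log\pi$ by $\log c$, which $\bar L$ absorbs into $B$; the
  $\ell$-values are unchanged. This is what makes results immune to
  radius-vs-diameter and radius-vs-squared-radius backend conventions.

## Hypothesis testing

Under the null "feature $p_i$ is noise", $\ell(p_i) \sim$ LGumbel, so the
observed value $x$ has p-value $e^{-e^{x}}$ (the complement of the null
CDF). Testing all $m = |\mathrm{dgm}_k|$ features simultaneously, the
package applies a Bonferroni correction and declares signal when
$p < \alpha/m$. Bonferroni is the only multiplicity rule shipped: it is
conservative, matches the framework's emphasis on family-wise control, and
suffices at the diagram sizes involved. $m$ counts every tested degree-$k$
feature of the current diagram, finite and infinite alike, recomputed
whenever the threshold changes.

### Infinite cycles

Computing a full filtration is often intractable, so diagrams are truncated
at a radius $\tau$; cycles born before but dying after $\tau$ are reported
as infinite. For such a cycle only the bound $\pi > \tau/b$ is available,
giving the p-value upper bound $e^{-e^{\ell(\tau/b)}}$ (the ratio pushed
through the $\ell$-map). The printed form of this bound mixes the $\pi$-
and $\ell$-scales if read literally; the implementation uses the only
reading consistent with the $\pi_{\min}$ relation and with the search
below, and the discrepancy is deliberately surfaced here rather than
resolved silently.

The search itself iterates: compute $D = \mathrm{dgm}_k(\tau)$; collect the
undecided infinite births $I = \{b : \tau/b < \pi_{\min}(\alpha/|D|)\}$,
where $\pi_{\min}(x) = \ell^{-1}(\log\log(1/x))$ is the smallest ratio
whose p-value reaches $x$; if $I$ is nonempty raise
$\tau \leftarrow \min(I)\,\pi_{\min}(\alpha/|D|)$ and repeat. The update is
strictly increasing by construction. Choosing the earliest undecided birth
($\min I$) keeps every intermediate complex as small as possible at the
price of more iterations; `pick = "max"` trades the other way. A cycle is
**certified** the moment its bound clears the Bonferroni level while it is
still infinite — the threshold at which this happens is recorded per cycle
(`tau_certified` in the trace), and is the quantity that measures the
method's savings: certification typically happens well below the cycle's
actual death scale, so the complex never has to grow to the death scale of
strong signal. Cycles that become finite along the way are handed to the
ordinary finite-feature test. Termination is guaranteed by a cap
`tauMax` (default: half the cloud diameter, at which a flag complex is a
cone and carries no cycles); hitting the cap with undecided cycles is
reported as non-convergence rather than hidden.

## The persistence engine

No persistent-homology backend ships with this R environment, so the
package carries its own:

* an **explicit flag engine** (C++): enumerates simplices up to the
  threshold through neighbourhood lists, assigns radius-scale values (Rips:
  half the largest pairwise distance; Čech: miniball radius, with facet
  clamping so floating-point miniballs never violate monotonicity), and
  reduces the boundary matrix over GF(2) with a lazy-column variant of the
  standard reduction — only columns that absorb additions are cached, which
  keeps multi-million-simplex reductions inside desk-scale memory. Degree 0
  is done by union-find.
* an **alpha-complex fast path** for planar clouds: Delaunay triangulation
  (via `interp`), circumradius values for triangles, half-length values for
  Gabriel edges and cofacet propagation otherwise. Its persistence equals
  the Čech filtration's, at linear complex size; the equality is asserted
  against the explicit Čech engine in the tests.
* a **reduction oracle** (`naiveRipsPersistence`): a deliberately simple,
  pure-R, global-boundary-matrix implementation capped at 64 points, used
  as an independent correctness reference — it shares no code with the
  engine.

Raw diagrams keep zero-persistence pairs and the degree-0 class born at 0;
`selectNoiseCandidates()` is the single point where those are dropped and
the finite/infinite partition is made, so the computation layer stays
faithful to the complex. Ratios numerically at 1 (within $10^{-12}$) carry
no log-log information and are dropped with a warning rather than mapped to
$-\infty$.

## What the samplers emulate — and what they do not

The generators cover iid uniform measures on solids and embedded manifolds
(box, ball, annulus with radii $[1/2, 1]$; sphere by normalised Gaussians;
torus with $R_1 = 2, R_2 = 1$; a Klein bottle and the projective plane in
$\mathbb{R}^4$; the Henneberg surface), iid products of beta, normal and
Cauchy coordinates, the configuration space of closed unit pentagonal
linkages (rejection sampling over two free angles, with an equal-probability
sign for the two circle-intersection branches of the last vertex), a
stratified plane-in-cube mixture, and two non-iid models: Brownian paths
(partial sums of iid Gaussian increments) and Lorenz trajectories with
$\sigma = 45, \rho = 54, \beta = 10$, sampled every $dt = 0.1$. The Lorenz
system is integrated adaptively (`deSolve::lsoda`) and read off on the $dt$
grid: a single fixed step of $0.1$ is unstable at these coefficients (the
local Lipschitz constant is of order $10^2$), and with $\rho$ below the
chaos threshold the trajectory in fact spirals into an equilibrium — the
sampler reproduces exactly that. Fixed-step `rk4`/`euler` with internal
substepping are exposed for anyone wanting a cruder integrator.

Mesh surfaces are sampled uniformly: triangles with probability
proportional to area, then barycentric placement. (Sampling *inversely*
proportional to area would concentrate points on slivers and is not a
uniform surface measure; the proportional rule is the one implemented.)

The figure-eight demo draws points uniformly on two unit circles tangent at
the origin, deletes a ball of radius $W/2$ around the origin to open the
neck, and adds Gaussian jitter. The jitter default is $\sigma = 0.01$,
about the mean inter-point spacing $4\pi/1000$ at the demo's sample size:
jitter at or below the sampling scale perturbs the curve without creating a
second, two-dimensional noise regime. That choice matters — jitter much
above the spacing blankets the curve in a dense band whose hundreds of tiny
loops inflate the Bonferroni denominator until genuine neck loops slip
below the correction — and is the package's own calibration of a
construction for which no canonical noise model exists.

Passing tests on these generators shows the machinery is correct and that
the null law holds across clean synthetic geometries at desk scale; it does
not by itself certify behaviour on real data with outliers, measurement
error, or strong anisotropy, nor for homogeneous (lattice-like or
repulsive) point processes, which are known not to follow the universal
law.

## Numerical choices

* All scales are radii; ties in the filtration order are broken by
  dimension, then lexicographically by vertex indices — deterministic
  across runs and platforms.
* The Čech triangle value uses the closed form (half the longest edge for
  obtuse triangles, circumradius otherwise); 4-point miniballs use a
  support-subset search with a $10^{-9}$ relative containment tolerance and
  are clamped from below by their facet values.
* The KS goodness-of-fit check is a plain one-sample test against the
  LGumbel CDF with the asymptotic p-value. Because $B$ is estimated from
  the same sample, the test is mildly conservative; the stochastic
  regression thresholds in the test suite were calibrated with this
  conservative test in place.
* Problem sizes in the test suite: engine-vs-oracle equivalence on clouds
  of up to 25 points (where the full Rips filtration is enumerable);
  distributional checks at $n = 2000$ with computation thresholds of
  0.08 (box Rips), 0.5 (torus) — chosen to sit above the largest typical
  noise deaths for those models so that the finite diagram is essentially
  the complete noise ensemble; error control on 100 pure-noise diagrams at
  $n = 1000$. These are the package's definition of desk scale: large
  enough for the law to show, small enough to re-run casually.
* Degenerate inputs: duplicate points produce zero-length degree-0 bars
  (kept, flagged); exactly cocircular planar inputs are fine for the
  square-corner style of example, but a large all-cocircular cloud is
  degenerate for the Delaunay construction and should go through the
  explicit Čech engine instead.

## Known limitations

* The full flag filtration grows cubically; the engine refuses untruncated
  computations beyond 300 points and expects a threshold instead. The
  alpha fast path is planar only — higher-dimensional alpha complexes
  (which would need a d-dimensional Delaunay construction) are not
  implemented, so Čech beyond the plane goes through the explicit engine
  with a threshold.
* $B$'s dependence on $(d, \mathcal{T}, k)$ is estimated per diagram, never
  modelled; no table of per-model intercepts is shipped.
* The per-feature test assigns no p-values to degree-0 features (the ratio
  statistic is undefined at birth 0).
* At $n \approx 2000$, borderline signal (ratio within a few percent of
  $\pi_{\min}$) can force the infinite-cycle search to its cap or past the
  signal's death scale; that is a property of the sample size, not of the
  algorithm, and the trace makes it visible (`converged`, per-cycle
  certification thresholds).
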