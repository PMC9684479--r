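---
title: "Span-of-regularization inversion for multi-exponential relaxometry: models, parameters and numerical choices"
author: "spanreg package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Span-of-regularization inversion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The inverse problem

Multi-exponential transverse relaxation data follow a Fredholm integral
equation of the first kind with a Laplace kernel: the measured decay is

$$y(t) = \int_{\tau_L}^{\tau_U} e^{-t/T_2}\, f(T_2)\, dT_2 ,$$

where $f \ge 0$ is the distribution function (DF) of relaxation times. On a
uniform $T_2$ grid of $n$ points with spacing $\Delta T_2$ and $m$ sampling
times, the discrete model is $\mathbf{y} = \mathbf{A}\mathbf{f}$ with
$A_{ij} = e^{-t_i/T_{2,j}}\,\Delta T_2$, so $\mathbf{f}$ carries density
units and areas are $\sum_j f_j\, \Delta T_2$. Signal-to-noise ratio is
defined as $\mathrm{SNR} = \max|\mathbf{y}| / \mathrm{RMS}(\omega)$ for
additive noise $\omega$; at the high SNR typical of the intended imaging
application, real i.i.d. Gaussian noise is an adequate approximation of
magnitude-image noise, and Rician corrections are out of scope.

Recovering $\mathbf{f}$ is a discrete inverse Laplace transform and is
severely ill-posed: on the default simulation configuration (200 grid
points in $[1, 200]$ ms, 150 times in $[0.3, 400]$ ms) the kernel's
condition number, measured as the ratio of extreme singular values,
exceeds $10^{15}$ — the double-precision floor of a spectrum that decays
essentially exponentially. Unregularized non-negative least squares (NNLS)
is correspondingly noise-dominated, and Tikhonov-NNLS,

$$\mathbf{f}_\lambda = \arg\min_{\mathbf{f}\ge 0}
  \|\mathbf{A}\mathbf{f}-\mathbf{y}\|_2^2 + \lambda^2\|\mathbf{f}\|_2^2,$$

trades noise sensitivity against resolution through the single weight
$\lambda$.

## The SpanReg estimator

Conventional selectors (discrepancy principle, L-curve, GCV) keep one
$\lambda$ and discard every other regularized solution. SpanReg instead
returns a non-negative combination across a ladder
$\lambda_1 < \cdots < \lambda_N$:

$$\mathbf{f}^*_\alpha = \sum_{j=1}^{N} \alpha_j^* \,\mathbf{f}_{\lambda_j}.$$

The weights come from matching two representations of the unknown DF in a
Gaussian dictionary $\{\mathbf{g}_i\}_{i=1}^M$ of unit-area atoms:

* **Offline** (per noise level, independent of the data): for each atom and
  each of $n_{\mathrm{run}}$ noise realizations, invert
  $\mathbf{A}\mathbf{g}_i + \omega$ at every ladder value, and average to
  get $\langle\mathbf{g}_{i,\lambda_j}\rangle$; fit each atom against its
  own per-realization inversions under non-negativity and average the
  coefficients to get $\langle\beta_{ij}\rangle$. One noise vector is drawn
  per (realization, atom) and shared across the ladder, matching the single
  $\omega$ that enters every term of the motivating identity.
* **Online** (per signal): compute the data's regularized family
  $\{\mathbf{f}_{\lambda_j}\}$, expand each member in the averaged basis
  ($x_{ij} \ge 0$), and solve the stacked problem

$$\min_{\mathbf{s} \ge 0,\ \sum c_i = 1} \|\mathbf{B}\,\mathbf{s}\|_2,
  \qquad \mathbf{s} = (\alpha_1,\dots,\alpha_N, c_1,\dots,c_M)^T,$$

with $\mathbf{B} = \mathbf{L}_\alpha\,\mathrm{diag}(\mathbf{x})\,
\mathbf{TT}_\alpha - \mathbf{L}_c\,\mathrm{diag}(\beta)\,\mathbf{TT}_c$
assembled from the Kronecker replication matrices. The simplex constraint
on $\mathbf{c}$ encodes the probability-distribution normalization of the
DF (unit area), which is also why phantoms are normalized to unit area
before synthesis and why imaging decays are rescaled first (below). The
stacked matrix is orders of magnitude better conditioned than
$\mathbf{A}$ itself (about $10^5$ versus $10^{16}$ and beyond), which is
what makes the weight estimation stable.

`spanreg()` returns both $\mathbf{f}^*_\alpha$ (the primary estimate — a
combination of solutions of the observed data) and the dictionary-side
reconstruction $\mathbf{f}^*_c$; the two are typically very close and
$\mathbf{f}^*_\alpha$ is used throughout.

## Default parameters

| Parameter | Default | Why |
|---|---|---|
| $T_2$ grid | 200 points, $[1, 200]$ ms, linear | 1 ms spacing; the study configuration |
| times | 150 points, $[0.3, 400]$ ms, linear | simulation layout; imaging uses $TE_i = i \times 11.3$ ms, 32 echoes |
| ladder | $N = 16$, log-spaced $[10^{-6}, 10]$ | spans distinctly-regularized solutions; config, not automated |
| dictionary | 160 atoms SD 2 + 40 SD 3 + 20 SD 4 ms, $M = 220$ | means equally spaced across $[\tau_L, \tau_U]$ inclusive |
| $n_{\mathrm{run}}$ | 50 | stabilizes the ensemble averages at the study SNRs; scaled runs noted below |
| $\nu_{DP}$ | 1.05 | discrepancy-principle safety factor |
| MWF window | $[6, 40]$ ms inclusive | short-$T_2$ (myelin water) pool |
| SNR bins | 18, geometric over $[10, 800]$ | noise impact is multiplicative in SNR |

Atom means are placed at `count` equally spaced positions spanning the grid
bounds inclusively — the placement rule itself is a design choice; spanning
the full support leaves no unilluminated edge. Edge-truncated atoms are
renormalized to unit discrete area so that $\sum c_i = 1$ keeps its
meaning. Time and $T_2$ grids are linearly spaced by default ("evenly"
spaced is read literally); log spacing is available as an option on the
$T_2$ grid.

## Numerical choices

* **NNLS core.** All constrained fits run through an active-set NNLS on the
  normal equations (FNNLS, Bro & de Jong style) implemented in compiled
  code, so the Gram matrix is amortized across the tens of thousands of
  right-hand sides the offline ensemble needs. Singular passive blocks fall
  back to a tiny ridge ($10^{-12}\,\mathrm{tr}/k$), then a pseudo-inverse.
* **Simplex-constrained solver.** The stacked problem (one equality, a
  non-negative orthant) is solved by a primal active-set quadratic program
  that keeps the equality in every working set; the equality holds to
  machine precision and ties/singularities use the same ridge rule. A
  penalty-row fallback (NNLS with a heavily weighted constraint row) is
  provided as an independent cross-check. Its weight is $10^3\|B\|$: the
  squared weight enters the normal equations, and a much larger weight
  pushes the data block below the double-precision noise floor of the Gram
  matrix. The penalty route is polished by one exact equality-constrained
  solve on the support it finds, after which the two routes agree to
  machine precision on test instances.
* **Discrepancy principle.** $\lambda_{DP}$ solves
  $\|\mathbf{A}\mathbf{f}_\lambda - \mathbf{y}\| = \nu\sqrt{m}\,\sigma$ by
  bisection on $\log\lambda$, using the monotonicity of the Tikhonov
  residual, to a relative tolerance of $10^{-3}$. The bracket is
  $[10^{-10}, 10^{4}]$ times the kernel's spectral norm; the spectral norm
  is the natural $\lambda$ scale here because the singular spectrum decays
  to the numerical floor, so interior statistics of the spectrum (for
  example its median) sit at roundoff and carry no scale information.
  Unreachable targets return the bracket endpoint with a flag instead of
  failing.
* **Oracle $\lambda$.** Simulation-only: the ladder value minimizing
  $\|\mathbf{f}_\lambda - \mathbf{f}_{\mathrm{true}}\|_2$, ties broken
  towards the larger $\lambda$ (more regularization at equal error).
* **$\sigma$ estimation.** For real decays, $\sigma$ is estimated as the
  SD of the last 20% of samples after mean removal, flagged when the tail
  is evidently not noise-dominated (tail mean above five tail SDs). In
  simulations the known $\sigma$ is used directly.
* **Peak counting.** A reconstruction "resolves" a component when it has a
  local maximum with topographic prominence at least 5% of the global
  maximum and at least 3 grid points of separation; both thresholds are
  arguments. Any such rule is a discretization of a visual judgement; the
  defaults match what a reader would call two distinct peaks on the 1 ms
  grid.
* **Stability triplets.** Stability under mis-selected regularization is
  quantified by re-running SpanReg restricted to three-$\lambda$ ladders
  $(\lambda/2, \lambda, 2\lambda)$ centred at shifted multiples
  $\lambda_{\mathrm{opt}} 2^{j}$ and comparing each reconstruction to the
  centred one. Other readings of "shifted combination" are possible (for
  example, reusing the centred triplet's weights on shifted solutions);
  re-running the full method on each triplet is the one implemented here,
  because it measures the stability of the whole estimator rather than of
  a frozen set of weights.

## The idealized limits and where they live

Two self-consistency properties — the noiseless, unregularized basis
collapsing to the atoms with $\beta \equiv 1$, and exact recovery of a
dictionary-member DF — hold in exact arithmetic only where the discretized
kernel has full numerical column rank. On fine grids the noiseless
zero-residual set is a polytope (the condition number is far beyond
$1/\varepsilon$), and an active-set solver legitimately returns a sparse
vertex of that polytope rather than the smooth atom; even the
best-regularized noiseless inversion of an SD-4 ms atom on the 200-point
grid keeps roughly 17% relative error. These properties are therefore
verified on coarse grids (8 and 12 points) where the kernel is numerically
full rank and the limits genuinely exist; the full-scale behaviour of the
method is covered by the noisy, comparative experiments instead.

## Myelin water fraction mapping

Imaging decays lack a $t = 0$ sample and are arbitrarily scaled, so each
pixel is normalized by the back-extrapolated $TE = 0$ amplitude of its
unregularized NNLS fit, $\sum_j f_{LS,j}\,\Delta T_2$ — an estimate that
introduces no regularization bias. The MWF is the fraction of the DF's
area inside $[6, 40]$ ms (a fraction, not a bare integral, so imperfect
normalization cancels). Maps are compared by the scaled absolute
difference $SAD(A,B) = \sum|A-B| / \sum|A|$. Because SNR varies across an
image, offline bases are precomputed per geometric SNR bin and each pixel
uses its bin's basis; pixel results are independent of evaluation order.

## What the synthetic generators emulate

`phantom_grid()` reproduces the two-Gaussian simulation lattice:
$\mu_1 = 35$ ms, $\sigma_1 \in \{2, 2.75, 3.5, 4.25, 5\}$ ms,
$\sigma_2 = 3\sigma_1$, and peak-separation ratios
$\mu_2/\mu_1 \in \{1, 1.75, 2.5, 3.25, 4\}$ — 25 DFs, none of whose
components coincides with a dictionary atom (checked in code). The printed
two-Gaussian density integrates to 2; phantoms are normalized to unit area
before synthesis because the simplex constraint assumes a probability
distribution, and the error metric is scale-invariant so comparisons are
unaffected.

`synth_phantom_stack()` builds a small image of concentric tissue-like
regions with two- or three-pool Gaussian DFs (a short pool inside the
myelin window plus longer pools), unit area per pixel, decays through the
32-echo kernel and per-pixel Gaussian noise on a geometric SNR gradient
over $[10, 800]$. It emulates the structure of a multi-echo relaxometry
acquisition — not acquisition physics: no stimulated echoes, no Rician
floor, no spatial correlation, no partial voluming. Passing tests on it
demonstrate the pipeline's behaviour under the stated noise model, not
performance on scanner data.

Per-cell simulation seeds derive as `master * 1000 + cell`, so any cell is
reproducible in isolation.

## Problem sizes used in the shipped checks

The package's own test suite runs the comparative experiments at the full
study configuration ($200 \times 150$ kernel, $M = 220$, $N = 16$, SNR
500) with ensemble sizes chosen for desk-scale runs: $n_{\mathrm{run}} =
10$ for the offline basis shared by the resolution and heat-map checks
(one basis serves all 25 phantoms — it depends only on kernel, dictionary,
ladder and noise level), $n_{\mathrm{run}} = 10$ per stability triplet,
and a reduced dictionary ($M = 60$, $N = 8$, $n_{\mathrm{run}} = 5$ per
SNR bin) with $10 \times 10$ phantom images for the mapping orderings.
The qualitative claims checked (orderings, resolution counts within their
stochastic bands) are stable at these sizes; the defaults
($n_{\mathrm{run}} = 50$) are recommended for production use.

## Known limitations

* SpanReg requires a (possibly approximate) noise level; that is shared
  with the discrepancy principle, and the SNR-binned bank shows coarse
  knowledge suffices, but fully blind use is not supported.
* The ladder and dictionary are configuration, not automatically selected;
  L-curve/GCV selectors are intentionally not implemented beyond the DP
  baseline.
* One-dimensional relaxometry only; 2D ($T_1$–$T_2$) extensions and
  complex-valued or Rician-corrected signal models are out of scope.
* Comparisons against scanner-derived reference MWF maps require real
  acquisitions; the shipped imaging checks use the synthetic phantom
  generator, which is labelled synthetic and makes no claim of anatomical
  realism.
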