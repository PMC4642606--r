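---
title: "Deflation, self-similarity, and the scaling of landmark shape variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deflation, self-similarity, and the scaling of landmark shape variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warpscaling)
```

## The model

A sample of n specimens, each a configuration of k homologous landmarks in
d = 2 or 3 dimensions, is first put into Procrustes shape coordinates by
`gpa()`: every specimen is centered, scaled to unit centroid size, and
iteratively rotated to the evolving mean until the mean stabilizes (full,
scaled superposition — variances are "in Procrustes units"). The converged
mean is standardized by `standardize_mean()`: centered, unit centroid size,
rotated to principal axes so that in 2D $\sum x_i y_i = 0$ with
$\alpha = \sum x_i^2 \ge \gamma = \sum y_i^2$ and $\alpha + \gamma = 1$.

The thin-plate spline of the mean supplies the scale structure. With kernel
$U(r) = r^2 \log r$ (2D; $U(0)=0$ by continuity) or $U(r) = |r|$ (3D), the
bordered system $L = \left(\begin{smallmatrix} K & Q \\ Q^t & O
\end{smallmatrix}\right)$ is assembled from the kernel matrix K and the
affine block $Q = (1\; x\; y\;[z])$, and the **bending-energy matrix** B is
the upper-left $k \times k$ block of $L^{-1}$. Its kernel is spanned by
exact planes $\{1, x, y[, z]\}$; the remaining $m = k-3$ (2D) or $k-4$ (3D)
eigenvectors $W_l$, sorted by ascending eigenvalue $E_l$, are the principal
warps, ordered from largest to smallest geometric scale. In 3D the block is
negative semidefinite; the package stores $-L_k^{-1}$ so both dimensions
share one positive-semidefinite code path. Note on normalization: with the
unnormalized kernel the literal plate integral
$\int (f_{xx}^2 + 2 f_{xy}^2 + f_{yy}^2)$ equals $8\pi\, V^t K V$;
`bending_energy()` reports the conventional $(1/8\pi) V^t K V$, and since
every downstream quantity is a ratio of energies, the constant never
matters.

**Partial warp scores** are the projections
$s_{jl} = W_l \cdot (\mathrm{aligned}_j - \mathrm{mean})$, one component per
Cartesian axis; under the isotropic offset Gaussian (Mardia–Dryden) model
their variances are equal across warps. **Deflation** (`deflate()`)
rescales warp $l$ by $(E_1/E_l)^p$ with $p = 1/2$ in 2D and $p = 1$ in 3D
(the kernel change alters the self-scaling exponent), leaving warp 1
untouched and dropping the uniform term, which has zero bending energy and
cannot be made commensurate. The result is self-similar: the nonaffine
variance of any sub-configuration, measured by a *fresh* Procrustes fit of
the subset (`subconfig_nonaffine_variance()`), is independent of the
subset's scale. Non-default exponents are exposed deliberately: they
generate synthetic integrated samples (e.g. $p = 1.1$ gives a variance
profile $\propto E^{-2.2}$), which is how the parameter-recovery tests and
the regime classifier are validated.

The **scaling dimension** is the slope of the unweighted OLS regression of
log partial-warp variance on log bending energy (`scaling_regression()`):
0 for isotropy, $-1$ for self-similarity, below $-1$ for integration.
The optional **nugget** $\nu$ (`scaling_regression_nugget()`) models
scale-free digitizing noise as an additive variance subtracted before the
log-log fit.

## Decisions made where the design was open

* **Nonaffine projection.** `project_nonaffine()` removes, per specimen and
  axis, the OLS projection onto $(1, x, y[, z])$ of the mean — i.e. it
  projects onto the span of the principal warps. Removing only the two
  closed-form uniform vectors would leave the $O(d^2)$ residual components
  along the rotation/scale directions that superposition cannot annihilate
  exactly, and would break the exact identity
  `reinflate(deflate(fit)) == project_nonaffine(fit)`. The closed-form 2D
  uniform rows (`uniform_basis()`) are still exposed — the second row is
  implemented as $(-\gamma x_1, \alpha y_1, -\gamma x_2, \alpha y_2,
  \ldots)$, the only pattern-consistent reading — and the regression route
  doubles as the 3D affine removal, where no convenient closed-form basis
  exists.
* **Rotation ambiguities.** The standardized mean's proper-flip ambiguity
  is fixed by giving the largest-radius landmark positive coordinates, axis
  by axis, the last axis absorbing the det = +1 constraint; eigenvector
  signs are fixed by making the largest-magnitude entry positive. All
  reported statistics are invariant to these conventions.
* **Nugget search.** The criterion is the SSE of the log-scale OLS — the
  most direct reading of "the fit is optimized" — minimized over
  $\nu \in [0,\ 0.999 \min v]$ by a 64-point grid plus golden-section
  refinement; a boundary optimum is flagged. The objective was unimodal on
  every synthetic family tested (checked against a 1024-point grid).
* **Regime classification.** No formal test is inherited, so the rule is
  declared: a 95% percentile bootstrap over specimens (default 1000
  resamples, seeded) for the slope; self-similar if the interval contains
  $-1$, integrated below, disintegrated above; fewer than 10 specimens
  yields "indeterminate". Warp subsetting remains a user decision —
  studentized residuals beyond 3 are flagged, never dropped automatically.
* **Relative intrinsic warps.** `relative_intrinsic_warps()` computes the
  ordinary PCA of the deflated coordinates; the generalized eigenproblem of
  the nonaffine covariance against the bending form exists in the test
  suite as an independent oracle, not as the implementation. Reinflated
  loadings multiply each warp component by the inverse prefactor and
  re-normalize. In 3D the deflated coordinates of the literal 3D deflation
  are used directly (equivalently, the relative eigenanalysis against the
  squared bending matrix). No automatic dimension-retention rule is
  applied.
* **The uniform "partial warp 0"** (`uniform_point()`) implements the
  worked plotting rule — displacement $\log(v_0/v_1)/\mathrm{slope}$ from
  warp 1's log energy — and labels its output heuristic, because the
  abscissa of a zero-energy term is genuinely indeterminate.
* **CLI.** The command-line front end is a function (`run_cli()`) with a
  thin Rscript wrapper in `exec/`, flags only (no config-file layer), so
  the whole surface is testable in-process and adds no dependencies beyond
  `jsonlite`.

## What the generators emulate

`isotropic_sample()` is the offset Gaussian: independent circular/spherical
noise of sd $\sigma$ at every landmark of a mean form.
`self_similar_sample()` is that sample superimposed and deflated.
`parcellation_sample()` is the hierarchical caricature of near
self-similarity: a unit-square template populated level by level (4 corners,
center, 4 edge midpoints, 4 quarter-cell centers — 4, 5, 9, 13 landmarks),
each new landmark placed at the location *imputed* by the thin-plate map of
all previously placed landmarks plus circular noise whose variance shrinks
by `decay` (default 1/2) per level. Its displacement fields are positively
autocorrelated between neighbours, unlike the isotropic model, and its
fitted scaling slope is near $-1$ by construction.

The toy means are reconstructions where the sources print none: the
six-landmark toy uses the unit square (landmarks 1–4, with 2 and 3
diagonally opposite) plus the two points completing the $\sqrt2$-scale
square on diagonal 2–3 — a layout validated by its bending-eigenvalue
ratios $1 : 1.069 : 2.145$; the 3D "giza" toy is two square-pyramid
pentahedra of base edges 4 and 1 sharing one apex (9 landmarks, scale ratio
4, apex height half the base edge). The quincunx and the 5×5 grid are exact.

What passing tests on these generators show — and what they do not: the
generators realize the *models*, with exactly circular digitizing noise,
exact landmark homology, and no directional, allometric, or group
structure. Agreement there validates the algebra and the estimators, not
the biological adequacy of any particular data set; real samples also bring
semilandmark spacing artifacts and measurement error that enter only
through the nugget term.

## Study conditions and numerical choices

The simulations used by the tests and the acceptance script run at the
conditions the reference quantities are stated for: the 5×5 grid with noise
sd 0.15 of the unit cell spacing and n = 1000 (slopes 0 and −1, 50-square
scale invariance, slope recovery for generating exponents 0, −1, −2.2);
the six-landmark toy at sd 0.05 of the unit edge and n = 1000 (the
pre-deflation variance halving of the larger square, post-deflation
equality, and the 75% trace after uniform removal — the source σ being
unprinted, only ratios are meaningful); the 3D pentahedra at sd 0.02 and
n = 500 (amplitude ratio 4 before deflation, 1 after); the parcellation
process at base sd 0.05, decay 1/2, n = 1000. The whole suite runs in well
under a minute on one core.

Numerical choices: eigenvalues below $10^{-9} \times$ the largest (in
magnitude) count as zero — scale-relative, robust across toys; one
factorization of $L$ is reused across the d height vectors of a map;
repeated eigenvalues on symmetric means (quincunx, grids) make individual
warps within an eigenspace basis-dependent, so every reported statistic
sums over eigenspaces or over all warps, and the per-eigenvalue variance
sums are convention-invariant; square detection on lattices uses exact
integer arithmetic (floating-point tests would miss the tilted,
"knight's-move" squares); TPS files are written with 15 significant digits
so round trips preserve at least 12. Where sampling noise at n = 1000
makes a literal "within 10%" bound on an extreme statistic a coin flip
(e.g. the largest of 25 per-landmark variance ratios), the tests assert
the calibrated version — the mean within the stated band, individual
values within three standard errors.

## Known limitations

Reflections are never fitted; semilandmarks are treated as fixed landmarks
(no sliding); the 3D uniform subspace is removed but never reported
componentwise (no closed-form basis); the deflation centers on the sample
Procrustes mean unless a template override is supplied; the scaling
regression is unweighted OLS on the log scale with no errors-in-variables
correction, so with very few warps the slope estimate inherits the full
sampling noise of the variances; and the classification bootstrap treats
specimens as exchangeable — longitudinal or phylogenetically structured
samples need a design-aware resampling scheme before the regime label can
be trusted.
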