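---
title: "Gradient-domain fusion of multimodal medical images: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient-domain fusion of multimodal medical images: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nablafuse)
```

## The problem

Complementary acquisitions of the same anatomy — CT and MR, or different MR
weightings — each show structure the other misses: bone and dense lesions in
CT, soft-tissue contrast in MR. Pixel-level fusion aims to combine two (or
more) co-registered single-channel images into one image that retains the
salient content of all sources. `nablafuse` does this in the *gradient
domain*: images are compared and merged where their information actually
lives, in their local derivatives, rather than in raw intensities.

The pipeline has three stages:

1. **Transform.** Each image $U$ is mapped to a vector field
   $(P, Q) = \nabla U$ by central differences with unit step,
   $P(x,y) = \tfrac{1}{2}(U(x{+}1,y) - U(x{-}1,y))$ and
   $Q(x,y) = \tfrac{1}{2}(U(x,y{+}1) - U(x,y{-}1))$, with $x$ indexing
   columns and $y$ rows. The operator is linear and annihilates constants,
   which the test suite checks as exact properties.
2. **Fuse.** The $n$ fields are merged pixelwise by one of three rules
   (below), giving a fused field $(\bar P, \bar Q)$.
3. **Reconstruct.** A scalar image with (approximately) those gradients is
   recovered by solving the discrete Poisson equation
   $\nabla^2 U = f$, $f = \partial_x \bar P + \partial_y \bar Q$, with
   Jacobi iteration under zero Dirichlet boundaries, then restoring the
   intensity offset (DC) that differentiation destroyed.

## Fusion rules

* **Weighted averaging** (`fuse_weighted`):
  $\bar P = \sum_i w_i P_i / \sum_i w_i$, the same for $Q$. Weights must be
  nonnegative with at least one positive; the default is equal weights,
  since no principled per-modality weighting is assumed.
* **Pointwise maximum** (`fuse_max`): the literal rule takes the signed
  maximum per pixel and component. Because a signed maximum discards strong
  *negative* gradients, a `magnitude` mode is also provided (largest
  absolute value, sign preserved, ties to the lowest source index); the
  signed form stays the default for fidelity to the published rule.
* **PCA weighting** (`fuse_pca`). The published description applies PCA to
  the per-pixel $n$-vectors $M_P(x,y)$, which is degenerate — one
  observation cannot support an $n \times n$ covariance. We adopt the
  standard reading that makes the eigenproblem well posed: for each
  component separately, the $n$ flattened component grids form the columns
  of a pixels-by-$n$ matrix, the covariance is estimated over all pixels
  (mean-centered, denominator pixels−1), and the leading eigenvector is the
  weight vector. Eigenvectors are sign/scale-ambiguous, so absolute values
  are taken and normalized to unit sum, making the weights a valid convex
  combination. A numerically zero covariance falls back to equal weights
  with a warning (once per component). Local or windowed PCA weight maps
  are deliberately out of scope.

## Reconstruction

Composing two central differences gives the *stride-2* second difference
$(U(i{-}2) - 2U(i) + U(i{+}2))/4$, and hence the linear system

$$4U(i,j) - U(i{-}2,j) - U(i{+}2,j) - U(i,j{-}2) - U(i,j{+}2) = b(i,j),
\qquad b = 4f,$$

iterated synchronously (true Jacobi, Gauss–Seidel is not used):
$U^{(m+1)} = (\Sigma_{\pm2\,\text{neighbors}}\, U^{(m)} + b)/4$.

Three numerical points deserve emphasis:

* **Sign of the right-hand side.** Rearranging the second-difference
  identity yields $\Sigma\,U - 4U = 4f$, i.e. the Jacobi form
  $4U - \Sigma U = b$ holds with $b = -4f$. `assemble_b()` keeps the
  published surface ($b = 4f$); `reconstruct()` feeds the solver $-b$. With
  any other sign the pipeline returns the *negated* image and no round trip
  can succeed. This is the only reading under which reconstruction inverts
  the transform, and the 64×64 round-trip tests confirm it (RMSE on the
  order of $10^{-4}$ at convergence).
* **Parity decoupling.** The ±2 stencil never couples pixels whose
  (row, column) parities differ, so the grid splits into four independent
  sub-lattices. This is implemented verbatim as the default
  (`paper_stride2`) because the published derivation is explicit about the
  stride; the conventional 5-point stencil (±1 neighbors, $b = f$, same
  sign handling) is available as `standard_5point`. A property test solves
  the four parity classes separately and confirms the joint solution is
  their sum. Note an asymmetry the spec did not anticipate: the stride-2
  solve inverts the composed differences *exactly* (up to iteration error),
  while the 5-point solve carries an $O(h^2)$ stencil mismatch — on smooth
  64×64 round trips both stay below RMSE 0.05, but stride-2 is the more
  accurate inverse, not the less.
* **Boundary band.** Pixels within the stencil stride of the border lack
  neighbors; they are held at the Dirichlet value 0 throughout (a band of
  width 2 under the stride-2 stencil, 1 under the 5-point). Reconstruction
  is therefore exact only up to a constant for images whose border band is
  constant — which the phantom generator guarantees by design — and the
  constant is repaired by DC restoration.

**Stopping.** The published analysis gives only the contraction factor
$cf(n) = \cos(\pi/(n+1))$ and the a-priori bound
$m > 2(1-\alpha)((n+1)/\pi)^2$. A bound alone is not a stopping rule, so the
solver stops on relative residual (max-norm of $4U - \Sigma U - b$ over the
interior, normalized by $\max|b|$ or 1) falling below `tol` (default 1e-6),
capped at `max_iter` (default: the a-priori bound at $\alpha = 0.01$).
Hitting the cap raises a classed warning, never an error. The linearized
bound is loose for small $\alpha$, so tight tolerances on large grids need
an explicit larger `max_iter`; tests pass one wherever they require deep
convergence.

**DC restoration.** The gradient field carries no intensity offset. The
default convention shifts the solution so its mean equals a reference — in
the full pipeline, the fusion-weighted mean of the source means (equal
weights for the max rule) — and `minmax` affine scaling to $[0,1]$ is the
alternative for display. Output is clipped to $[0,1]$.

## Quality metrics

The published evaluation names its metrics without defining them; one
canonical convention is pinned here and used everywhere:

| metric | convention |
|---|---|
| entropy | Shannon entropy, 256 equal-width bins on $[0,1]$, bits |
| STD | population standard deviation |
| average gradient | mean over interior of $\sqrt{(g_x^2+g_y^2)/2}$, central differences |
| edge intensity | mean Sobel gradient magnitude, replicate borders |
| MI | sum over sources of $I(F; S_i)$ from 256×256 joint histograms, bits |
| SSIM | uniform 7×7 window, population moments, $K_1=0.01$, $K_2=0.03$, $L=1$, valid windows, averaged over sources |
| Qabf | Xydeas–Petrović edge transfer: Sobel strength/orientation, sigmoid parameters $(0.9994, -15, 0.5)$ and $(0.9879, -22, 0.8)$, strength-weighted average over both sources |

One Qabf detail is a deliberate package choice: the orientation difference
is folded modulo $\pi$ (an edge's direction is axial) before the sigmoid.
The unfolded arctan-branch form is not invariant under transposing all
images together; folding restores that exact symmetry and keeps the
agreement term in $[0,1]$. Edge-free source pairs define Qabf as 0 with a
warning. Reference-based and externally defined measures (Piella $Q_E$,
phase-congruency $Q_p$, Chen's and Wang's metrics) are out of scope.

## Statistical comparison of fusion methods

Methods are compared over $N$ samples (one per experiment × metric) by the
Friedman protocol, with rank 1 = best within each sample (so better methods
have *lower* mean ranks) and average ranks on ties:

* $\chi^2_F = \frac{12N}{k(k+1)}\big[\sum_j \bar r_j^2 - k(k+1)^2/4\big]$,
  and its F form $F_F = (N-1)\chi^2_F / (N(k-1) - \chi^2_F)$ on
  $(k-1),\,(k-1)(N-1)$ degrees of freedom. Both p-values are reported. The
  equivalent sums-of-squares form $Q = SS_t/SS_e$ is implemented
  independently and equals $\chi^2_F$ on tie-free data to $10^{-10}$
  (property-tested). At the ceiling $\chi^2_F = N(k-1)$ (a perfectly
  consistent ranking) the F form degenerates; `friedman_F()` treats that as
  an error per its contract, while the wrappers report $F = \infty$,
  $p = 0$.
* **Critical differences**: $CD = c \cdot \sqrt{k(k+1)/(6N)}$ with two
  critical values: the Siegel–Castellan $z$ at upper-tail
  $\alpha/(k(k-1))$, computed from the normal quantile rather than read off
  a coarse printed table, and the two-tailed Bonferroni–Dunn value,
  computed as $t_{1-\alpha/(2k),\,N-1}$ — the closed form behind the usual
  printed Bonferroni tables (for $k=9$, $N=36$, $\alpha=0.05$ it gives
  2.955, inside the 2.931–2.988 bracket those tables print). Significance
  requires a difference strictly *greater* than CD.
* **Step procedures vs the best method**: two-sided normal p-values
  $p_i = 2(1-\Phi(|R_i - R_{best}|/SE))$, ordered ascending; Holm
  (step-down: reject until the first $P_j > \alpha/(k-j)$) and Hochberg
  (step-up: reject through the last $P_j \le \alpha/(k-j)$). Hochberg's
  rejection set provably contains Holm's, which is property-tested on
  random p-vectors.

Orientations are declared per sample row in the `score_matrix`; every
bundled metric is higher-is-better.

## The synthetic world

No external imaging data ships with the package; generators produce all
test inputs deterministically from a seed (the pinned repository seed is
20230816).

* `make_phantom_pair()` emulates a co-registered CT/MR pair at 64×64 for
  tests (256×256 is the demo scale matching typical atlas images): source A
  gets a bright ring ("skull") plus compact high-contrast shapes in the
  upper angular sectors; source B gets smooth soft-tissue shading with
  low-frequency texture plus shapes in the lower sectors, so the masks are
  disjoint by construction. The outer margin (default 8 px) is exactly
  constant, making zero-Dirichlet reconstruction exact up to DC. What the
  phantoms do *not* emulate: anatomical realism, registration error,
  noise, intensity nonuniformity. A green round-trip test therefore
  establishes the correctness of the transform/solve machinery, not
  clinical performance.
* `make_gradient_case()` returns a smooth image (Gaussian bump, or a
  harmonic bilinear ramp) with its exact transform, for round trips.
* `make_score_matrix()` plants target mean ranks via per-method base scores
  one rank-unit apart plus Gaussian noise (default sd 0.5, half the gap —
  enough to scramble adjacent methods without erasing the ordering). With
  zero noise the planted permutation is recovered exactly; with the default
  noise, the all-equal planting stays non-significant for Friedman in 96 of
  the 100 pinned seeds, and a strongly dominant method is recovered (best
  mean rank, Friedman significant) in 100 of 100.

## Degenerate inputs and tie-breaks, in one place

* images smaller than 3×3 (or 5×5 for the stride-2 solve), or non-finite
  pixels: rejected with informative errors;
* all-zero weights or any negative weight: rejected;
* magnitude-max ties: lowest source index wins;
* PCA on all-zero fields: equal weights + warning;
* Jacobi non-convergence: classed warning, result returned;
* `minmax` DC restoration of a constant solution: returns the reference
  constant;
* Qabf with edge-free sources: 0 with warning; `friedman_Q` with all rows
  fully tied: degenerate-statistic error;
* rank ties: average ranks, preserving row sums $k(k+1)/2$.

## Limitations

Single-channel rectangular images only; no registration, no DICOM/NIfTI,
no TIFF (no reader in the supported stack — PNG and plain PGM are the
formats, with 16-bit via PGM); Jacobi only as the production solver (a
dense direct solve exists solely as a test oracle); the stride-2 stencil's
parity decoupling means independent sub-lattice solutions — faithful to the
published derivation, but a conventional 5-point solve is one flag away.
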