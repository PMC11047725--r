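---
title: "From surface point clouds to body volume and weight: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From surface point clouds to body volume and weight: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cloudvol` estimates the volume of a closed object — in the motivating
application, a live pig scanned by depth cameras — from a surface point
cloud, and maps volume to body weight through a linear model. This vignette
explains the model at each stage, the tunable parameters, the synthetic
world the package is validated against, and the design choices made where
the method left genuine latitude.

## Pipeline overview

A raw cloud passes through five stages:

1. **MLS smoothing** removes burr noise by projecting each point onto a
   locally fitted polynomial surface.
2. **PCA normal estimation** recovers the normal *line* at each point from
   the smallest-variance direction of its neighbourhood covariance.
3. **MST orientation** chooses consistent normal *signs* by propagating
   along a maximum spanning tree of a similarity-weighted KNN graph.
4. **Screened Poisson reconstruction** solves for an indicator function
   whose gradient matches the oriented normal field, then extracts a
   watertight triangle mesh at an adaptive iso-threshold.
5. **Tetrahedral summation** turns the closed mesh into a volume;
   optionally a fitted linear model turns volume into predicted weight.

## Smoothing

For each point, a weighted PCA plane over its $k$ nearest neighbours
defines a local frame; a bivariate polynomial height field is fitted by
weighted least squares with Gaussian weights
$w(d) = \exp(-d^2/h^2)$, $h = \text{bandwidth} \times \bar d_k$, and the
point moves to the fitted surface along the plane normal.

The underlying formulation prescribes the weighted least-squares objective
but not the projection rule, and is written for a generic scalar field. We
project along the local plane normal with a full bivariate quadratic basis:
this basis is closed under in-plane rotations, so the result does not
depend on the arbitrary tangent frame, and the smoother commutes with rigid
motions to machine precision (a property the tests assert at $10^{-8}$).
Polynomials up to the basis degree are reproduced exactly, so planes and
paraboloids are fixed points.

Defaults: $k = 30$, quadratic basis, bandwidth 2. The quadratic basis in
3-space has 10 terms, so the configuration rejects $k < 10$; $k = 30$
leaves a comfortable margin. Rank-deficient local fits (e.g. collinear
neighbourhoods) fall back to a plane projection with a warning, and a
fitted displacement larger than the neighbourhood radius is treated the
same way — smoothing may never move a point further than its neighbourhood.

## Normal estimation and orientation

The covariance is taken about the query point itself,
$C = \tfrac1k X^\top X$ with rows $x_i - x_0$, and the normal is the
eigenvector of the smallest eigenvalue — the direction of least projection
variance. Signs are then fixed globally: the KNN graph (default $k = 10$)
gets edge weights $E(i,j) = \psi(i,j)\,\omega(\lVert x_i - x_j\rVert)$ and
the maximum spanning tree of $E$ is traversed from a seed, flipping a child
normal when its inner product with the (corrected) parent normal is
negative.

Two $\psi$ variants are provided. *Distance* mode uses
$\psi = |\langle n_i, n_j\rangle|$. *Tangency* mode first removes from
$n_i$ its component along the edge direction; an edge lying in the tangent
plane changes nothing (the two modes coincide on flat patches — a test
asserts this), while an edge running parallel to the normals, e.g. jumping
across a thin plate, gets weight near zero and is avoided by the tree.
Absolute values are used during tree construction because signs are exactly
what is still unknown; sign decisions happen during traversal.

Design choices left open by the formulation:

* $\omega$ is unspecified beyond "decays with distance"; we use
  $\exp(-d^2/h^2)$ with $h$ the mean KNN distance.
* The seed is the point of maximal $z$, its normal forced to negative dot
  with $+z$: the interior lies below the topmost point, which realizes the
  *inward* normal convention adopted throughout. Inward is the opposite of
  the more common outward convention; a single global sign relates the two,
  and the volume stage takes an absolute value, so no result depends on it.
* The maximum spanning tree is computed as a minimum spanning tree on
  negated weights (igraph).

One honest finding from the thin-plate stress fixture (a closed
$1 \times 1 \times 0.05$ box sampled at spacing 0.02, with light burr
noise): tangency weighting mis-orients no more points than distance
weighting, and keeps both large sheets internally consistent and mutually
opposite — but the dramatic failure where distance weighting flips an
entire sheet does not materialize under our Gaussian $\omega$, which
suppresses the cross-gap shortcut edges so strongly that the spanning tree
never takes them. The superiority of tangency weights here is a margin, not
a cliff; the tests assert the inequality, not the cliff.

## Screened Poisson reconstruction

The indicator $\chi$ (high inside, low outside) satisfies
$\Delta\chi = \nabla\!\cdot\!\vec V$ where $\vec V$ is the smoothed inward
normal field. The *improved* variant adds a position constraint: the energy

$$E(\chi)=\int \lVert\nabla\chi - \vec V\rVert^2 \,dp
  \;+\; \lambda\,\frac{\mathrm{Area}(S)}{\sum_p \tau(p)} \sum_{p\in S}\tau(p)\,\chi^2(p)$$

pulls $\chi$ at the samples toward the surface level, weighted by the
per-sample credibility $\tau(p)\in[0,1]$: the mean over $n$ neighbours of
$g(\cos\theta)$, where $\theta$ is the angle between neighbouring normals,
$g(x)=x$ on $[0,1]$ and $0$ below. Well-agreeing neighbourhoods get
$\tau \approx 1$; conflicted ones (occlusion boundaries, noisy legs) are
down-weighted.

Discretization. The octree over the padded bounding cube (10% padding)
defines the function space; samples are splatted into it with
tensor-product quadratic B-spline weights (the three-fold box convolution —
the smooth, compact basis the formulation points to), and the indicator is
represented on the complete depth-$D$ level, a $2^D$-per-axis lattice. The
linear system is the 7-point finite-difference Laplacian (Neumann) plus the
mass-lumped, $\tau$-weighted position term on the diagonal:
$(L + \alpha\,\mathrm{diag}(W_\tau))\,\chi = -\nabla_h\!\cdot\!\vec V$.
We deliberately use the finite-difference Laplacian rather than the
quadratic-B-spline Galerkin stiffness matrix: at a fixed lattice both are
second-order accurate, and the 7-point stencil is about six times cheaper
per iteration — the difference between the depth-8 end-to-end runs fitting
their CPU budget and not. All solver arithmetic is in grid units, which
makes reconstruction exactly equivariant under similarity transforms of the
input (volume scales by the cube of the factor; asserted at 0.5%).

Numerical choices:

* **Solver**: conjugate gradients with a geometric multigrid V(2,2)-cycle
  preconditioner (lumped-Galerkin hierarchy, damped-Jacobi smoother),
  relative residual $10^{-8}$; iteration counts stay around 10–20 even at
  depth 8 ($256^3$). Grids below $64^3$ use Jacobi-preconditioned CG
  directly.
* **Nullspace**: with $\lambda = 0$ the Neumann system is defined up to a
  constant; the right-hand side is projected to zero mean and the mean of
  $\chi$ is pinned to zero. The iso-threshold makes results invariant to
  this choice.
* **$\mathrm{Area}(S)$** has no formula in the source method ("the
  reconstruction area near the input sample point"). We implement it as the
  root-cube face area in grid units. An alternative per-sample surrogate
  (face area divided by $|S|$) makes the position term about $10^{-4}$ of
  the gradient term at depth 8 — numerically indistinguishable from plain
  Poisson, which defeats the constraint's purpose — so the area-scale
  surrogate was chosen; it keeps the two energy terms on comparable scales
  at every depth.
* **$\lambda$ and $n$** are never given numerically; defaults are
  $\lambda = 4$ (the interpolation-weight scale customary in screened
  reconstruction practice) and $n = 10$ for the $\tau$ neighbourhood. Both
  are exposed.
* **$\tau$ placement**: the position term is weighted by $\tau$ exactly as
  the energy above states; splatting $\tau$-scaled normals instead is
  available through the `weights` argument of `splat_vector_field()` but is
  not the default.
* **Iso-threshold** $\mu_{iso}$ is the mean of $\chi$ over all sample
  positions, evaluated through the same B-spline basis.
* **Contouring**: marching *tetrahedra* on the $2^D$ lattice (six
  tetrahedra per cell around a globally consistent diagonal). Unlike
  classic marching cubes it has no ambiguous cases, so the extracted
  surface is watertight by construction — a hard requirement, since the
  volume stage refuses non-watertight input. The cost is a higher facet
  count per cell; facet counts still grow monotonically with depth.

## Volume

Each face plus a common origin spans a tetrahedron of signed volume
$\tfrac16\det[a-o,\,b-o,\,c-o]$; for the origin this determinant expands to
the familiar six-term expression the tests cross-check term by term. Over a
closed, consistently wound mesh the signed contributions cancel outside the
solid, so the absolute sum is the volume — independent of the origin and of
whether it lies inside. Winding consistency is repaired by breadth-first
propagation across shared edges; the global sign per component comes from a
reference cloud's normals when given (nearest-point majority vote) and
otherwise from requiring positive signed volume. Degenerate (zero-area)
faces contribute nothing and are tolerated silently — marching output
contains them routinely.

The *slicing baseline* bins points along an axis, takes each slab's 2D
convex-hull area, and sums area × thickness (default thickness: the
minimum point spacing). The convex hull is the reproducible contour choice,
and its failure on concave cross-sections is exactly the documented failure
mode of the method: on the L-prism fixture the baseline overestimates by
construction (hull area 0.875 vs true 0.75 per unit height) while the
mesh route stays within 1%.

## The synthetic world

Real scans of 479 pigs are unavailable, so validation runs on generated
fixtures whose ground truth is exact:

* **cube** (side 1, analytic volume 1), **cylinder** ($r=h=1$, volume
  $\pi$), **sphere** (Fibonacci-spiral sampling), **L-prism** (concave,
  volume 0.75), **thin plate** (closed $1\times1\times0.05$ box, the
  orientation stress case).
* **piglet**: ellipsoid torso and head plus four capsule legs, surfaced
  from the implicit union (minimum of part signed-distance functions) by
  marching tetrahedra at a fixed resolution. The ground truth is the
  tetrahedral-summation volume of that constructive mesh — an exact mesh
  boolean union is not available without a CSG dependency, and the
  marching-extracted union mesh plays the same role; it is additionally
  cross-checked against an independent parity-count voxelization oracle
  (0.5%). The piglet is *synthetic*: it emulates the role of a scanned
  model, it does not reproduce any particular animal.
* **corruption**: Gaussian jitter along normals (burr noise), a fixed
  fraction of outlier burrs, and box-shaped occlusion (a leg hidden by a
  railing). Sampling is stratified per face/patch rather than uniform —
  scanner output is grid-like, and stable densities help the
  reconstruction at fixed point counts. The stratified jitter defaults to
  0 (regular grids), matching point clouds exported by CAD/scan tooling.
* **volume–weight tables**: volumes uniform on $[0.0791, 0.1249]$ — the
  published weight range 83–132 kg mapped back through the published line
  $y = 1070.4x - 1.6524$ — and weights $y = a v + b + \mathcal N(0,
  \sigma)$. The default $\sigma = 4.1$ kg is calibrated in closed form, not
  by simulation: with signal standard deviation
  $a\,(v_{max}-v_{min})/\sqrt{12} = 14.15$ kg, $R^2 = 0.921$ requires
  $\sigma = 14.15\sqrt{1/0.921 - 1} \approx 4.1$. The resulting Pearson
  correlation, $\sqrt{0.921} \approx 0.96$, sits within rounding of the
  published 0.95.

What a green test does **not** establish: the generators contain no sensor
model (no depth-dependent noise, no registration misalignment between
camera views, no ground/railing clutter), the piglet is far simpler than
pig geometry, and the volume–weight table assumes the linear relation it
is then shown to recover. Synthetic results validate the *algorithms*, not
field performance.

## Quartiles and other small conventions

Error quartiles use linear interpolation between order statistics
(quantile type 7) — the box-plot convention had to be pinned for testing.
Relative error is always a percentage of the actual weight. The intercept
formula is read as $\bar y - a\bar x$ (the only consistent least-squares
reading). KNN ties break toward the lower point index, spanning-tree ties
toward the earlier edge, so every stage is deterministic at fixed seed.

## Known limitations

* The solver stores the full $2^D$ lattice: depth 8 uses about 1.5 GB of
  working memory; depth 12 is accepted by the API but impractical on
  desktop memory (the octree's adaptive node sets are built, but the
  complete-level solve is not sparse).
* Marching tetrahedra produces 3–5× the facet count of marching cubes at
  equal resolution; meshes are correct but not economical.
* Orientation assumes one dominant connected component; disconnected
  clouds are oriented per component with a warning, but the inter-component
  sign relation is arbitrary.
* The slicing baseline supports only convex-hull contours, by design.
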