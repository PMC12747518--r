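---
title: "Models and methods behind gyralkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gyralkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gyralkit simulates cortical folding as a mechanical instability driven by
differential tangential growth, and quantifies and compares the resulting
folded surfaces with shape-index morphometry and landmark-matched
quasi-conformal disk maps. This vignette explains the models, the
numerical choices, and what the synthetic study conditions do and do not
establish about real brains.

## The growth model

A developing brain is modeled as a soft elastic solid in which a thin
superficial layer (gray matter) expands tangentially relative to the bulk
(white matter). Growth enters through the multiplicative decomposition of
the deformation gradient,

$$\mathbf F = \mathbf A\,\mathbf G, \qquad
  \mathbf G = \sqrt g\,\mathbf I + (1-\sqrt g)\,\mathbf n\otimes\mathbf n,$$

where $\mathbf G$ expands area by factor $g$ in the plane perpendicular to
the local growth normal $\mathbf n$ (no growth along $\mathbf n$), and
$\mathbf A$ is the elastic part that actually stores energy. The tissue is
modestly compressible neo-Hookean,

$$W = \frac{\mu}{2}\left(J_A^{-2/3}\,\mathrm{tr}(\mathbf A^{\mathsf T}
 \mathbf A) - 3\right) + \frac{K}{2}\,(J_A-1)^2,
 \qquad J_A = \det\mathbf A,$$

with $K = 5\mu$ by default. This is the standard isochoric/volumetric
split: $W = 0$ exactly when $\mathbf A = \mathbf I$ (i.e. when the body
deforms exactly as its growth prescribes) and $W \ge 0$ otherwise, by the
arithmetic-geometric mean inequality.

Both the shear modulus and the growth ratio follow the same sigmoid
profile in the *reference* distance $d$ to the cortical surface,

$$\mu(d) = \mu_w + \frac{\mu_g - \mu_w}{1 + e^{10(d/h - 1)}},\qquad
  g(d) = g_w + \frac{g_g - g_w}{1 + e^{10(d/h - 1)}},$$

so the "cortex" is the layer $d \lesssim h$, with a smooth transition of
relative width $\sim h/10$. The cortical thickness $h(t) = h_0 -
h_\text{slope}\,t$ thins slowly over normalized time $t\in[0,1]$. Default
parameters are the ferret-like study conditions: tangential expansion
1.8 at the cortical surface, $g_w = 1$, stiffness ratio
$\mu_g/\mu_w = 1$, $K/\mu = 5$, $h(t) = 0.1 - 0.005\,t$ on a geometry
normalized so the half longitudinal extent is 1.

A note on the growth-ratio convention, because two incompatible ones
circulate. In the tensor above, $g$ is the *areal* factor
($\det\mathbf G = g$) and the in-plane stretch is $\sqrt g$. The older
simulation literature this model descends from quotes the *linear*
tangential expansion instead. The two readings differ materially: an
areal factor of 1.8 produces an elastic surface strain of only
$1 - 1/\sqrt{1.8} \approx 0.25$, which sits below the creasing threshold
of an equal-stiffness bilayer ($\approx 0.33$–$0.35$) — we verified by
converged runs at three mesh resolutions that no folds can form there,
while a quoted ratio of 1.8 read as the linear expansion (areal factor
$1.8^2 = 3.24$) folds robustly. `growth_config()`'s `g_g` is always the
areal factor of the formula; its default, `1.8^2`, corresponds to a
quoted growth ratio of 1.8 in the linear convention.

### Quasi-static relaxation

The solver is an explicit, damped relaxation of the total energy
$\sum_e V_e\,\det(\mathbf G_e)\,W_e$ over linear (P1) tetrahedra with
one-point quadrature; forces are the exact analytic negative gradient
(verified against central finite differences in the test suite). Growth
is applied in areal increments of at most `max_g_increment` (default
0.05, about 2% of the default total) with full relaxation between
increments (quasi-static stepping). Each step integrates
$v \leftarrow (v + \Delta t\,f/m)(1-\gamma)$,
$x \leftarrow x + \Delta t\,v$ with light velocity damping
$\gamma = 0.05$. Because the problem is quasi-static, nodal masses are
free parameters: we use dynamic-relaxation mass scaling — each node's
mass is the sum of its elements' stiffness scales
$(K + \tfrac43\mu)V_e/h_e^2$ ($h_e$ the smallest altitude) — which
equalizes elemental frequencies and makes $\Delta t = 0.3$ stable and
mesh-independent; with physical masses the same solver needs orders of
magnitude more iterations.

Three safeguards keep the iteration honest:

* **Inversion guard.** A step that would make any $\det\mathbf F \le 0$
  is rejected; the state reverts to the best energy seen, velocities are
  zeroed and $\Delta t$ halves.
* **Window monotonicity.** A step whose energy exceeds the value 100
  iterations earlier (beyond $10^{-6}$ relative) is likewise rejected, so
  the recorded energy trace is non-increasing across any 100-iteration
  window. If $\Delta t$ collapses by a factor $10^6$ the run is declared
  divergent and the last stable state is returned with a warning.
* **Stopping.** Iteration ends when the maximal nodal force drops below
  `force_tol` (default $10^{-3} \mu_{\max} \bar A_b$, with $\bar A_b$
  the mean boundary-triangle area) or when the energy has been flat to
  $10^{-8}$ relative over 100 iterations (a plateau far below any
  mechanically meaningful change), capped at `max_iters` per increment.

Self-contact of folding gyri is a vertex–triangle penalty on the boundary
surface only: quadratic in the penetration past `contact_range` (default
0.6 of the mean boundary edge; stiffness $2\mu_{\max}\times$ mean edge),
with candidate pairs from a uniform spatial hash refreshed every 10
iterations and triangles in the vertex's immediate 1-ring excluded. By
the envelope theorem the penalty force is the exact gradient of the
penalty energy at fixed pair set, so the finite-difference force check
covers it.

### Protocols

Under the **continuous** protocol, the reference (stress-free)
configuration is the initial geometry throughout, and the surface growth
ratio ramps linearly from 1 to $g_g$ over $[0, t_\text{end}]$. Under the
**step-wise** protocol, at each configured stage time the current deformed
geometry is adopted as the new stress-free reference: shape matrices, the
distance field and growth directions are recomputed on the deformed mesh
and accumulated elastic energy drops to exactly zero (this mimics
re-initializing from observed intermediate geometries). Each of the $k$
stages then applies a multiplicative share $g_g^{\Delta t_j/t_\text{end}}$
of the total growth, so the product over stages recovers $g_g$; the
thickness schedule may be given per stage. This share rule is our
reading of a two-stage schedule with a single printed total ratio; it is
the only one of the obvious conventions under which the stages compose to
the stated total.

The growth normal $\mathbf n$ at an interior point is the direction to
its nearest reference boundary point, frozen per stage. Non-growing
regions (an occipital-pole-like mask) are supported through an optional
per-vertex factor multiplying $g - 1$.

## Synthetic study geometries

No real imaging data ships with the package; a seeded generator produces
brain-like solids. The mesh is a layered icosphere ball: concentric
icosphere shells joined by triangular prisms (split into conforming
tetrahedra via smallest-global-index quad diagonals), with the innermost
shell coned to the center. The ball is mapped to an ellipsoid with the
longitudinal semi-axis first, and the boundary is perturbed by a seeded
band-limited radial field — a random mixture of real spherical harmonics
up to degree `n_modes`, scaled so the maximal radial displacement is
`amplitude * min(semi_axes)` and decaying quadratically toward the center.
The perturbation stands in for the smooth undulations of a real fetal
surface, whose amplitude is not well constrained; we default to
`amplitude = 0.03`–`0.05`, small enough to preserve genus and tet
positivity, large enough to break the ellipsoid's symmetry and seed
fold nucleation. Everything is a pure function of its arguments,
including the seed.

The folding study used by the acceptance script runs the ferret-like
conditions (tangential expansion 1.8, stiffness ratio 1, thickness
$0.1 - 0.005t$) on an elongated ellipsoid with semi-axes
$(1, 0.65, 0.55)$ — ferret brains are roughly twice as long as they are
tall — meshed as a two-shell + cone-core ball of 20,480 tets with
boundary edge $\approx 0.11$: fine enough tangentially to resolve crease
wavelengths $\sim 0.4$, coarse enough to run in minutes on one CPU.
Convergence comparisons against a coarser surface (8,960 tets, edge
0.22, which under-folds) and against finer radial layerings (35,840 and
51,200 tets, which agree with the chosen mesh) fixed this resolution;
the mesh sizes are stated here as the package's study conditions. The
growth is applied in areal increments of 0.05 (about 2% of the total),
with seeded symmetry-breaking noise of 0.15 of the mean boundary edge
before each relaxation — the creasing instability is subcritical, so a
perfectly smooth compressed state is a legitimate equilibrium and folds
need a finite seed to nucleate.

At this scale the folded surface's shape-index histogram is bimodal
with the rut mode within one bin of $-0.5$ and the ridge mode near
$+0.55$, slightly above the ideal $+0.5$: desk-scale gyri ride on a
body whose own curvature ($\sim 1/L$) is only an order of magnitude
below the fold curvature, so the "straight" principal direction of a
gyral crown still curves with the body and biases the ridge shape index
upward by a few hundredths. The bias shrinks as the scale separation
between folds and brain size grows (real brains have much more of it),
and is stable across seeds.

What the synthetic conditions do *not* emulate: regionally varying
growth maps, anatomical lobes, hemispheric asymmetry, white-matter
anisotropy, and the skull. Passing tests therefore establish the
mechanics and the measurement chain, not anatomical fidelity.

## Morphometry

Discrete curvature uses the standard cotangent toolkit: Gaussian
curvature as angle defect over the mixed Voronoi area, mean curvature as
half the magnitude of the cotangent-Laplacian mean-curvature normal,
signed by the outward vertex normal. With this convention $H > 0$ on
outward-convex (gyral) crowns, which makes gyral nodes score shape index
near $+1$; the sign convention is a package choice, checked by the
orientation-flip test. Boundary vertices have no defect-based estimate
and are masked out of histograms and similarity fields.

The shape index

$$\mathrm{SI} = \frac{2}{\pi}\arctan\!\frac{H}{\sqrt{H^2 - K}}$$

is scale-free and classifies local shape from cup ($-1$) through saddle
(0) to cap ($+1$); ridges and ruts sit at $\pm 0.5$. At umbilic points
$H^2 - K \to 0$ and the index degenerates to $\pm 1$; numerically we use
`umbilic_tol` ($10^{-12}$ at unit mesh scale) on $H^2-K$, return
$\mathrm{sign}(H)$ inside it, and 0 when $H^2$ is also below tolerance
(planar). Discretization can produce $H^2 < K$ slightly; such values are
clamped to the umbilic limit and counted. Five-class counts use the open
intervals with deterministic tie-breaks ($\pm 0.5$ to the saddle-side
class, exact 0 to "saddles"). Histograms are over 64 equal bins on
$[-1,1]$, smoothed with a Gaussian kernel of 1.5 bins; modes are local
maxima with topographic prominence at least 0.1 of the global maximum.
On a folded surface the histogram is characteristically bimodal near
$\pm 0.5$ with the ridge mode dominant; on a sphere the index is 1
everywhere (umbilic).

## Disk mapping and similarity

Simply connected open surfaces (validated by explicit counting:
$\chi = 1$, one boundary loop, oriented edge-manifold) are flattened to
the unit disk: the boundary loop maps to the circle with
arclength-proportional spacing and the interior by discrete harmonic
extension with cotangent weights (negative weights clamped to a small
positive floor, so the result is a Tutte embedding — convex boundary plus
positive weights guarantees no flipped triangles). A few correction
passes re-space the boundary by the measured boundary conformal factor
and re-solve; the iterate with the smallest mean $|\mu|$ is kept and its
distortion reported. On a smooth hemisphere this is near-conformal
(mean $|\mu| < 0.1$); on strongly folded surfaces it remains a valid
embedding with larger distortion.

Quasi-conformal machinery is standard: the per-face Beltrami coefficient
$\mu = f_{\bar z}/f_z$ of the piecewise-linear map ($|\mu| < 1$ iff
orientation is preserved), and a least-squares reconstruction that finds
the map minimizing $\sum_f A_f\,|f_{\bar z} - \mu_f f_z|^2$ subject to
point constraints (hard constraints eliminated, soft ones penalized).
With a compatible $\mu$ and enough pins the residual is zero — an affine
map is recovered exactly from its coefficient and two pins.

Landmark matching pulls the moving disk's landmark curves onto the
reference's: curves are resampled at 20 points of equal normalized
arclength, expressed as edge points of the reference triangulation, and
constrained softly toward their targets; the boundary is pinned to the
circle. The constraint weight ramps up (and the achieved $\mu$, clamped
at 0.95, feeds back as the target) until the worst landmark mismatch
falls below `tol` or orientation would be lost; the residual is always
reported. Soft constraints were chosen over hard interpolation because
the landmark tolerance/formulation is a free design choice and soft
weights degrade gracefully when curves are far apart.

The similarity of two surfaces compares a field $I \in [-1,1]$ (shape
index or rescaled mean curvature $\tilde H = 2(H-\min H)/(\max H - \min
H) - 1$) on the reference vertices against the comparison field pulled
back through $g_2^{-1}\circ f_{12}\circ g_1$ by barycentric
interpolation on the target disk:

$$s = 1 - \frac{\|I_1 - I_2\circ\phi\|_p}{2\,m^{1/p}},\qquad
  p \in \{1, 2, \infty\},$$

which lies in $[0,1]$ because both fields are bounded by 1. The
comparison is asymmetric (the reference surface fixes the domain), both
directions can be computed, and $m$ counts the reference's non-boundary
vertices with valid curvature — boundary estimates are unreliable, and
the choice is recorded in every report. The rescaled mean curvature's
range is taken over interior vertices, with boundary values clamped into
$[-1,1]$ for interpolation.

## Degenerate inputs and tie-breaks

Zero-area triangles abort curvature estimation with the face index;
constant fields are rejected by the rescaler; cut vertices exactly on the
dissection plane go to the kept side; the dissection warns if it produces
more than one boundary loop; points that spill outside the target disk
during pull-back are projected to the nearest boundary point first.
Mesh files are ASCII (OFF/PLY/STL surfaces, legacy VTK and node/ele
volumes, CSV fields, JSON landmarks), written with 17 significant digits
so geometry and connectivity round-trip; indices are 0-based on disk and
1-based in memory.

## Problem sizes and limitations

The shipped tests and the acceptance script run entirely from synthetic
geometry at desk scale: curvature oracles on icospheres up to
subdivision 4 (2,562 vertices), the folding study at 20,480 tets, slab
bilayer fixtures at a few thousand tets, and mapping fixtures on
hemispheres of a few hundred vertices. At these sizes the folding
patterns are mesh-influenced (a few elements per crease wavelength) and
only statistical features of the fold geometry — area expansion, the
bimodal shape-index histogram, the dominant ridge mode — are meaningful;
individual fold positions are not. The explicit solver is robust but
first-order; very stiff contact or growth increments far above 0.02
demand smaller steps. The hemisphere dissection of a deeply folded
surface can produce multiple boundary loops (a cut through a buried
sulcus), which the validator reports; such surfaces need a different cut
plane before disk mapping.
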