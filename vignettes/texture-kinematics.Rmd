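---
title: "Texture-tensor kinematics of epithelial tissue: model, estimators and simulator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-tensor kinematics of epithelial tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A confluent epithelial monolayer is treated as a two-dimensional tiling of
polygonal cells. Its deformation is described on two coupled levels:

* **Tissue level.** A velocity field $v(t, r)$ with gradient
  $\nabla v$ whose symmetric part $G = (\nabla v + \nabla v^T)/2$ is the
  tissue strain rate and whose antisymmetric part $\Omega$ is rigid
  rotation. Over a frame interval $\Delta t$ the deformation gradient $F$
  satisfies $\nabla v = (F - I)/\Delta t$ and
  $G \simeq (F^T F - I)/(2\Delta t)$.

* **Cell level.** A symmetric positive-definite $2\times 2$ cell-shape
  tensor $M$ (units of squared length) whose eigenstructure is the
  coarse-grained cell ellipse; cell area is $A = \pi|M|^{1/2}$ and number
  density $\rho = 1/A$.

Tissue strain decomposes into the strain produced by cell shape change (S),
rearrangement (R), division (D) and apoptosis (A):

$$G = S + R + D + A, \qquad D_T = R + D + A,$$

with S the elastic part and the topological terms plastic. The two kinematic
identities the package evaluates are

$$\dot M = (\nabla v - D_T)\,M + M\,(\nabla v - D_T)^T$$

for the shape tensor (Lagrange derivative) and, as its determinant
consequence,

$$\partial_t \rho + \nabla\cdot(\rho v) = (\mathrm{Tr}\,D_T)\,\rho$$

for the density. Both contain no mechanical parameters: properly measured
tensors must satisfy them, which is what makes them useful cross-checks of
the measurement pipeline itself. Because rearrangement conserves area,
$\mathrm{Tr}\,R = 0$ is expected, with $\mathrm{Tr}\,D \ge 0$ and
$\mathrm{Tr}\,A \le 0$.

## Measuring M: the texture tensor and its normalization

For an ROI $P$ the unnormalized texture tensor sums outer products of
half-links (center-to-center vectors $l_{ik}$, each undirected pair counted
in both directions with a factor $1/2$, weight $\omega_{ik} = 1$ for edge
contacts and $1/2$ for fourfold-vertex contacts, links to outermost cells
excluded):

$$\hat M^{(0)} = \sum_{i \in P} \tfrac12 \sum_k \omega_{ik}\, l_{ik}\otimes l_{ik}.$$

$\hat M^{(0)}$ grows with the number of cells and is therefore not a
cell-shape tensor. The package's default is the half-link-normalized

$$\hat M^{(1)} = \hat M^{(0)} / N_h,$$

with $N_h$ the number of half-links; $\hat M^{(2)} = \hat M^{(0)}/N_c$
normalizes per cell instead. $N_h$ counts half-links (each undirected pair
twice when both endpoints are members, once when one endpoint lies outside
the ROI); the weights $\omega$ do not enter $N_h$. With this convention
$\hat M^{(1)}$ is ROI-size invariant on homogeneous tissue (coefficient of
variation below 5% from 10 to 200 cells in the test suite) and agrees with
pixel-based second moments without any fitted factor. Two further
normalization variants are exposed as registration points
(`registerTextureVariant`) rather than concrete formulas, because their
exact definitions involve additional neighbor-count sums that the package
does not presume.

The pixel route computes per-cell second moments from the label raster and
applies the factor 4 that maps an ellipse's moment to its squared semi-axes
($m_{xx} = r_a^2/4$ for an axis-aligned ellipse); the test suite verifies
this factor to better than 1% on a 120-px-semi-axis raster. Cell areas are
reported in two conventions — contour pixels excluded, and half
(1/n for n-fold contacts) of the adjacent contour pixels included; the
half-included convention is the faithful one for density comparisons, since
the excluded convention undercounts each cell by roughly half its perimeter
in pixels.

On a regular hexagonal tiling with center spacing $d$, $\hat M^{(1)} =
(d^2/4) I$ exactly and the tensor area $\pi d^2/4$ underestimates the true
cell area $(\sqrt3/2)d^2$ by $\pi/(2\sqrt3) \approx 0.907$ — the intrinsic
offset of the ellipse approximation for hexagons, worth remembering when
absolute areas matter.

## Strain estimators

**Deformation gradient.** $F$ is the least-squares affine transport of the
conserved half-links, $F = B C^{-1}$ with $C = \sum (\omega/2)\, l_t\otimes
l_t$ and $B = \sum (\omega/2)\, l_{t+\Delta t}\otimes l_t$. It is exact for
affine motion (machine precision in the tests) and unbiased under isotropic
link noise. This differs from texture-difference constructions by terms of
order $\Delta t^2$, the same order as the discretization itself.

**Decomposition.** Appearing and disappearing half-links are classified per
event: all links created or destroyed by a division (mother links,
daughter–daughter link, links re-pointed from mother to daughter) are D
under the default division-priority rule; the alternative rule re-labels the
re-pointed links R, and measurably degrades the density balance on
division-rich scenes — the package keeps division-priority as default and
the alternative as an explicit option. Links of a dying cell and the new
contacts closing its vacancy are A (the latter configurable to R); remaining
exchanges between surviving cells are R.

Each class X contributes an increment of the half-link-normalized texture

$$\Delta \hat M_X = \frac{1}{\bar N_h}\Big[\sum_{\text{app},X}
\tfrac{\omega}{2} l'\otimes l' - \sum_{\text{dis},X} \tfrac{\omega}{2}
l\otimes l\Big] \;-\; \frac{\Delta N_{h,X}}{\bar N_h}\, \hat M_{mid},$$

where $\bar N_h$ is the mean half-link count of the two epochs and the
second term carries the change of the normalization count attributable to
the class. This term is essential: without it a division (which adds links
while making cells smaller) would be assigned a negative trace, breaking
both the sign contract $\mathrm{Tr}\,D \ge 0$ and the density balance. With
it, the identity $\Delta \ln\rho/\Delta t + \nabla\cdot v =
\mathrm{Tr}\,D_T$ holds to second order by construction, which the tests
confirm with regression slopes within a few percent of 1 through both
divergence routes ($\mathrm{Tr}\,G$ and PIV).

The symmetric rate of class X solves the Sylvester relation
$-\Delta\hat M_X = (T_X \hat M_{mid} + \hat M_{mid} T_X)\,\Delta t$ with
$\hat M_{mid}$ the mid-interval tensor (centered differencing); for a
$2\times2$ SPD $\hat M_{mid}$ the solution is a closed-form $3\times3$
linear solve and always unique.

**Closure.** In `raw` mode S is measured independently as the Sylvester
solution of the full change of $\hat M^{(1)}$, and the closure residual
$G - (S+R+D+A)$ is reported; on smooth irrotational scenes the residual
strain falls by a factor $\approx 4$ when $\Delta t$ halves. With a
rotational flow component the raw residual floors at
$O(\Omega\cdot\text{anisotropy})$, because the method deliberately excludes
rotational deformation from the decomposition ($\Omega$ is computed as a
diagnostic only). In `strict` mode $S := G - (R+D+A)$ and the closure is
exact by construction.

## Velocity measurement and tracking

The PIV implementation is single-pass windowed FFT cross-correlation
(64-px windows, 16-px steps by default) with a three-point sub-pixel peak
fit, an n-standard-deviation outlier filter with local-median replacement
(n = 3 default), and a texture mask that invalidates windows whose intensity
variation falls below half the image's. One numerical caveat drove a design
decision: one-pixel contour imagery has a near-delta autocorrelation, which
locks the sub-pixel fit onto integer displacements (errors up to 0.5 px).
A Gaussian pre-smoothing of sigma = 1 px (default, `preSmooth`) widens the
correlation peak and restores ~0.15 px accuracy. Velocity gradients come
from a least-squares plane fit of the vectors in the ROI's bounding box;
fits touching the tissue boundary are unreliable because partially empty
windows bias toward the textured side, so boundary ROIs should be excluded
from velocity-route comparisons (the tests do).

Cell tracking advects centers with the velocity field and solves the gated
linear assignment problem exactly (`clue::solve_LSAP` on an augmented square
matrix in which every cell may stay unmatched at cost `maxDist`²,
realizing the infinite-cost gate). The default gate is 400 px, appropriate
for large-format imagery; on synthetic scenes a cell-scale gate (about half
a cell diameter after advection) is the right setting, because a forced
perfect matching otherwise chains through intervals containing both a
division and an apoptosis. Divisions are detected by assigning each new cell
the matched neighbor with the largest area decrease (ties: smallest center
distance, then lowest id); unmatched interior cells are apoptoses, unmatched
outermost cells "left the field". ROIs are Lagrangian: membership at the
next frame is the lineage image of the current membership, so no cell ever
transfers between ROIs and finite differences of per-ROI quantities are
Lagrange derivatives.

## The synthetic-tissue simulator

The simulator provides ground truth, not mechanics: tilings are advected
passively through a prescribed flow (affine, or bilinear on a coarse grid)
and topological events are applied by exact surgery on the shared-vertex
polygon mesh. Cell polygons always partition the same outer boundary, so
total area is conserved exactly under T1s and divisions and redistributed
under T2s. Default conditions mirror the analysis setting of segmented
pupal-epithelium movies: a few hundred Lloyd-relaxed Voronoi cells of
~25 px diameter, strain rates of order 0.01/min, minute-scale frame
intervals, 120–140 px ROI tiles holding ~20–30 cells, and event rates of a
few per interval (a percent-scale fraction of cells).

Two design points deserve explanation:

* **T1 realization.** A passive simulator has no junction mechanics, so the
  near-fourfold configurations from which real neighbor exchanges proceed
  never arise spontaneously. T1 sites are therefore *selected* where the
  junction is closest to fourfold symmetry in the texture metric — the
  $M^{-1}$ inner product between the separating-pair and joining-pair
  center distances, the joining pair evaluated at its measurement epoch —
  and the edge is ramped through the exchange: shrunk to 12% of its length
  in the frame before the swap, swapped at that length, regrown one
  interval later. This realizes the area-neutrality of rearrangement
  ($\mathrm{Tr}\,R = 0$) that the kinematics asserts; an instantaneous
  full-length swap (available via `t1Ramp = FALSE`) is measurably
  area-non-neutral (normalized mean $\mathrm{Tr}\,\hat R \sim -0.2$ instead
  of $|{\cdot}| \lesssim 0.01$).

* **Division and T2 geometry.** Division splits the polygon through its
  centroid, by default perpendicular to the long axis; daughters inherit
  the mother's neighborhood and share a new edge. T2 collapses the cell to
  its centroid, creating a multicell junction whose point contacts carry
  weight 1/2. Neither event relaxes the neighborhood afterwards, which is
  the main respect in which the simulator is *less* realistic than tissue:
  real junctions re-equilibrate within minutes. Consequently passing tests
  certify the bookkeeping and the kinematic identities, not mechanical
  realism; rates, shapes and anisotropies of real tissue are outside what
  the simulator validates.

Scenes are reproducible bit-for-bit from their configuration and seed; the
event log, exact velocity samples and per-interval deformation gradients are
stored alongside the frames.

## Numerical choices and edge cases

* Tensors are computed in px² and converted to physical units only at
  reporting (`pixelSize` slot), keeping image-side tests exact.
* Eigenvalues are ordered $\lambda_1 \ge \lambda_2$; orientations are axial
  in $(-\pi/2, \pi/2]$; isotropic tensors return NA with a flag rather than
  an arbitrary angle. Orientation coherence is
  $|\langle e^{2i\theta}\rangle|$.
* ROIs with fewer than 3 non-collinear half-links are flagged degenerate
  and rejected by all tensor operations; ROI intervals that lose their
  conserved-link support are skipped with a message, never silently zeroed.
* Rasterization carves one-pixel contours alternating sides on a
  checkerboard so pixel-mean centers stay unbiased (within 0.5 px of the
  polygon centroid at 20 px cell diameter); labels equal cell ids.
* Fourfold vertices on rasters are junction pixels whose 3×3 neighborhood
  shows four labels; the diagonal pairs without edge evidence elsewhere get
  ω = 1/2 point contacts. Point contacts at higher-order junctions (e.g.
  after a T2 collapse) are treated the same way.
* Moving averages (30-min and 3-min defaults for time series, 200-px
  windows at 50-px spacing for kymographs) are centered; windows without
  data yield NA, never zero.
* Problem sizes in the shipped tests — 120–300-cell tilings, 5–20
  intervals, one PIV pair per interval — were chosen as the smallest scenes
  on which every property is statistically unambiguous.

## Known limitations

* Rotational deformation is excluded from the decomposition by design; raw
  closure residuals on rotating tissue reflect that, not an error.
* Single-pass PIV (no window deformation or multi-pass refinement) limits
  velocity accuracy under strong strain to roughly
  $|\nabla v| \cdot \text{window}/2$ per vector.
* The tracker has no gap closing or multi-hypothesis reasoning; a lineage
  produced elsewhere can be supplied in its place.
* The simulator's tilings are flat, confluent and passively advected; no
  curvature, no free boundaries inside the field, no mechanics.
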