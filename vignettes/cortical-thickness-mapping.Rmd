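---
title: "Mapping cortical thickness between dissimilar FE meshes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cortical thickness between dissimilar FE meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortimap)
library(dplyr)
```

`cortimap` transfers a per-node cortical-bone thickness field from a solid
source mesh to a shell target mesh of different anthropometry and
tessellation. This vignette records the model behind each stage, the
parameters that matter, the numerical conventions, and the design choices
made where the problem is genuinely open — the things a maintainer would
want to know before changing anything.

## 1. Thickness extraction from a solid layer

The source cortical layer is one element thick: every node lies on either
the outer (periosteal) or inner (endosteal) surface, and every solid
element joins one face on each. Thickness lives naturally on the outer
nodes. For outer node $j$ with paired inner node, the inner-to-outer vector
$\mathbf d_j$ is generally *not* perpendicular to the surface — element
columns cross the layer obliquely wherever the two surfaces are not locally
parallel. Using $|\mathbf d_j|$ directly would overestimate thickness
there, so $\mathbf d_j$ is projected onto the outward unit vertex normal
$\hat{\mathbf n}_j$:

$$ t_j = |\mathbf d_j \cdot \hat{\mathbf n}_j|
       = \alpha_j \, |\mathbf d_j|, \qquad
   \alpha_j = \frac{\mathbf d_j \cdot \hat{\mathbf n}_j}{|\mathbf d_j|}. $$

The absolute value guards against inconsistently labelled surfaces
producing negative thickness; by Cauchy–Schwarz $0 < t_j \le |\mathbf
d_j|$ always. Nodes with $|\alpha| < 0.2$ (near-tangent columns, usually a
meshing defect) and nodes at or below the thickness floor ($10^{-6}$ mm)
are flagged in a QC attribute rather than rejected — degenerate geometry is
a modelling question the code should surface, not silently answer.

**Pairing.** The default pairing is topological: within each element, an
outer node's partner is the inner-face node sharing an element edge (the
same column of a hexahedron; wedge vertices pair across the two
triangles). Nodes shared by several elements must pair identically in all
of them, otherwise the layer is malformed and the error names the node. A
nearest-inner-node fallback (`pairing = "nearest"`) exists for layers whose
element-local ordering cannot be trusted; on the concentric-shell fixtures
the two agree exactly.

**Vertex normals** are area-weighted averages of incident face normals
(angle weighting is an option; on smooth near-uniform tessellations the two
differ negligibly). For a closed surface the outward sign comes from the
enclosed signed volume, after an orientation pass that makes windings
mutually consistent — so a mesh whose faces are all wound backwards yields
identical normals. For an open surface, where "outward" is genuinely
undefined, the dominant component of the mean normal is made positive; this
is a documented convention, not a geometric fact. For solid layers no
convention is needed: each outer face is oriented away from its element's
centroid.

## 2. The dual-Kriging morph

Matched landmark sets $\{\mathbf x_r\} \to \{\mathbf y_r\}$ (hand-picked
anatomical sites in both models) drive a smooth map applied to every source
node. Per output coordinate the map is an affine *drift* plus a radial
*fluctuation*:

$$ f(\mathbf x) = a_0 + a_1 x + a_2 y + a_3 z
   + \sum_{s=1}^n b_s\, K(\lVert \mathbf x - \mathbf x_s \rVert),
   \qquad K(h) = h^2 \log h,\; K(0) = 0. $$

The $n+4$ coefficients per coordinate solve the symmetric bordered system
with the side conditions $\sum_s b_s = 0$ and $\sum_s b_s \mathbf x_s =
\mathbf 0$. These conditions are essential and easy to omit: without them
the system is underdetermined (the drift and fluctuation can trade off
against each other) and the solution is not unique. With them:

* the map **interpolates** — every retained source landmark lands exactly
  on its target (tests assert $<10^{-8}$ mm);
* an **affine** correspondence is absorbed entirely by the drift
  ($\lVert b\rVert_\infty < 10^{-8}$), so global size/pose differences
  never leak into the nonlinear term;
* the map is translation-equivariant.

$K(h) = h^2\log h$ is the classical choice for landmark morphing in
biomechanics; linear, cubic, Gaussian and (inverse) multiquadric kernels
are exposed as options (`kind =`), with the shape parameter of the latter
two defaulting to the median inter-landmark distance. Distances enter $K$
in raw millimetres; `rescale = TRUE` centres and scales to a unit
bounding-box diagonal before solving (useful for badly conditioned
landmark clouds) and agrees with the raw solve to better than $10^{-6}$ on
well-scaled problems.

### Control-point optimisation

Digitisation error or ambiguous anatomy can make individual landmarks hurt
the morph. `optimize_control_points()` removes them greedily. Scoring
needed one real design decision: because the morph interpolates whatever
points drive it, the naive "RMSE of all retained landmarks" is identically
zero and can never justify a removal. The score used is therefore
cross-validated: a candidate retained set is scored by the RMSE over *all*
original pairs, where each retained point contributes its leave-one-out
error (refit without it, evaluate at it) and each removed point its probe
error under the candidate fit. A corrupted landmark is then caught not by
its own residual (its probe error is a constant floor in every score) but
by the distortion it inflicts on every other point's cross-validated
error — which disappears the moment it is dropped. Rounds accept the
removal with the largest RMSE reduction, ties broken by lowest landmark
index for determinism, and stop when the best improvement falls below 1%
of the current RMSE (absolute floor $10^{-9}$ mm): gains below
landmark-digitisation precision should not strip consistent points. The
accepted-RMSE trace is non-increasing by construction. On a fixture with
one landmark displaced 10 mm, that landmark is eliminated in round one; on
an exactly-affine correspondence nothing is removed.

**Morph quality** is summarised as the distribution of $q_i$, each target
node's distance to the nearest morphed source node (mean ± SD, max), plus
the landmark RMSE in millimetres after morphing. Note the landmark RMSE of
an interpolating morph is numerically zero by definition; it becomes
informative only after optimisation has set some landmarks aside.

## 3. Projection and the choice of $\beta$

With source and target in one frame, every target node $i$ takes the
weighted mean of all $N$ morphed source thicknesses:

$$ t_i^F(\beta) = \frac{\sum_j t_j\, q_{ij}^{-\beta}}
                      {\sum_j q_{ij}^{-\beta}}, \qquad
   q_{ij} = \lVert \mathbf x_i^F - \mathbf x_j^M \rVert . $$

$\beta = 0$ is the uniform source mean; $\beta \to \infty$ the
nearest-neighbour transfer. Numerics: log-weights $-\beta \log q_{ij}$ are
shifted per target node by their maximum before exponentiation, so the
largest weight is always 1 and $\beta = 50$ on sub-millimetre distances
cannot overflow. A target node
coincident with a source node takes that node's thickness exactly (the
analytic zero-distance limit; the mean if several coincide) rather than an
epsilon-inflated weight. Every projected value is a convex combination of
source values; projections are invariant to source ordering and to global
scaling of all coordinates (weights are ratios of like powers). All source
nodes contribute — no cutoff radius — per the defining formula; the full
$P \times N$ distance work is chunked and is negligible at the problem
sizes this package targets.

### Accuracy and smoothness

Two normalised metrics govern $\beta$. *Accuracy* compares each projection
to the $\beta_{\max} = 50$ anchor (treated as the perfect, most consistent
transfer):

$$ A(\beta) = 1 - \frac{\sum_i (t_i(50) - t_i(\beta))^2}
                      {\sum_i (t_i(50) - t_i(0))^2}, $$

so $A(0)=0$ and $A(50)=1$ exactly. *Smoothness* measures how noisy the
field is around its local first-order spatial gradient: at each node a
linear model $\hat t_m = C_1 x_m + C_2 y_m + C_3 z_m + C_4$ is least-squares
fitted to the thicknesses of the $m$ edge-connected neighbours (the node
itself excluded — the regression predicts the connected nodes from their
coordinates), and $E_i = \lVert \hat t - t \rVert^2$. A constant or
globally linear field gives $E_i = 0$ everywhere. With $m < 4$ neighbours
or rank-deficient coordinates the minimum-norm solution keeps the residual
well defined; isolated nodes get $E_i = 0$ with a warning. The normalised
distance of the error vector to the noisy anchor,
$\sum_i(E_i(50)-E_i(\beta))^2 / \sum_i(E_i(50)-E_i(0))^2$, equals 1 at
$\beta=0$ and 0 at $\beta=50$; we call it the **smoothness retention** and
report as the smoothness metric its complement $S(\beta)$, which runs from
$S(0)=0$ to $S(50)=1$ — the degree to which the projection has moved into
the noisy nearest-neighbour regime. Both orientations are returned
(`smoothness()` attaches the retention as an attribute; the sweep table
carries both columns) since the two conventions coexist in practice and
only differ by $1-x$.

In the mid-$\beta$ range the reported $S$ need not be monotone: moderate
exponents can produce *larger* regression errors than the
nearest-neighbour transfer itself, because inverse-distance weights with
small $\beta$ develop the classic bulls-eye artifact around each source
node while a nearest-neighbour field is piecewise constant. The anchors
are exact regardless; only the interior of the curve is data.

### The tradeoff point

The selected exponent is where rising accuracy meets falling smoothness
retention: the smallest crossing, by piecewise-linear interpolation on the
sorted grid, of $A(\beta)$ and $1 - S(\beta)$. The retention curve is the
one used because the reported $S$ shares both endpoints with $A$ (both 0 at
$\beta=0$, both 1 at the anchor), making an $A$-vs-$S$ crossing degenerate,
whereas $A$ vs retention runs from $(0, 1)$ to $(1, 0)$ and always crosses;
on the two-point grid $\{0, 50\}$ the interpolated crossing is exactly
$\beta = 25$. The default grid $\beta \in \{0, 1, 2, 3, 4, 10, 25, 50\}$
concentrates points where the projection actually changes; the anchor
$\beta_{\max} = 50$ is configurable. On the reference fixture the crossing
falls just below 3 — the same neighbourhood where accuracy saturates and
the retention collapses.

```{r sweep, eval = FALSE}
spec <- fixture_spec(level = 2, seed = 1)
src  <- make_solid_shell(spec)
pair <- make_target_pair(spec, bulge_deformation())
field <- nodal_thickness(src$layer)
src_nodes <- morph_mesh(src$surface,
                        fit_kriging(pair$landmarks_source,
                                    pair$landmarks_target))$nodes |>
  inner_join(field[, c("node_id", "thickness")], by = "node_id")
sw <- beta_sweep(pair$target, src_nodes)
autoplot(sw)
```

## 4. What the synthetic fixtures do and do not show

Real source/target geometries of this kind are proprietary, so the package
generates its own study conditions with exact ground truth:

* **Geometry**: icosphere-tessellated sphere (default radius 10 mm, the
  scale of a small curved bone region) or ellipsoid; subdivision level 2
  (162 outer nodes / 320 wedges) by default, level 3 (642/1280) for
  convergence checks. Icospheres have near-uniform valence 6, matching the
  neighbour-regression's assumptions about mesh regularity.
* **Thickness field**: the latitudinal default
  $t(\theta) = 1.5 + 0.5\cos\theta$ mm spans 1–2 mm, the range that covers
  most of a real coxal cortical surface; `constant` and seeded Gaussian
  `bumps` variants exist. The inner surface is the outer offset along
  analytic normals, so extraction can be compared to the exact field.
* **Target**: a re-tessellated copy (different level, or the same level
  with a seeded tangential jitter of 0.25 mean edge lengths so nodes never
  coincide) pushed through a known smooth deformation — affine, or a
  radial bulge (default amplitude 15%, angular width 0.6 rad) standing in
  for an anthropometry change. The pre-image parameters give the exact
  thickness at every target node and the exact deformed position of every
  source node.
* **Landmarks**: 24 farthest-point-spread surface sites (well-spread, as
  hand-picked anatomical points would be), with optional Gaussian noise
  and a single injected outlier for the optimiser tests. One seed fixes
  everything; identical seeds yield byte-identical exported files.

Passing on these fixtures demonstrates the algorithmic contracts —
interpolation, affine reproduction, convergence under refinement,
oracle-equivalence of the metrics — on smooth, closed, well-meshed
geometry. It does **not** demonstrate robustness to the pathologies of
production anatomical meshes: sliver elements, non-manifold junctions,
sharp ridges where vertex normals are ambiguous, landmark placement error
fields that are spatially correlated rather than i.i.d., or genuinely
different cortical distributions between individuals (the transfer assumes
the source's distribution applies to the target). The end-to-end test
(extract → morph → project at $\beta = 4$) recovers the analytic field
within 5% of its dynamic range at level 3 and improves monotonically over
levels 1–3; those sizes keep the whole suite under a minute on one core.

## 5. File formats and conventions

LS-Dyna keyword I/O covers `*NODE`, `*ELEMENT_SOLID`, `*ELEMENT_SHELL`,
`*ELEMENT_SHELL_THICKNESS`, titled `*SET_NODE_LIST` and `*END`, with `$`
comments; cards may be comma-separated or fixed-width, and the writer
emits comma-separated cards (unambiguous) with nine significant digits —
round-trip safe beyond the six the thickness contract requires. Node ids
are 1-based. Wedges are encoded as collapsed hexahedra (positions 3/4 and
7/8 repeated) and reconstructed on read. Inner/outer surface sets are
taken from `*SET_NODE_LIST_TITLE` cards named `OUTER`/`INNER` when
present; otherwise the two cap-node families are derived from element
topology and the larger-area family is labelled outer — correct for any
closed shell offset inward, and an error (requesting explicit sets) when
the topology does not produce exactly two families. Legacy ASCII VTK
(POLYDATA) and Wavefront OBJ cover surface meshes; landmark sets are CSV
with header `label,x,y,z`. Quadrilateral shell faces are accepted and
split on the 1–3 diagonal for normals/adjacency only; stored connectivity
is preserved on output. Millimetres throughout; no unit conversion is ever
applied.

## 6. Known limitations

* Landmark-driven only: no surface-based registration refinement, so morph
  quality in regions far from any landmark is unconstrained.
* The $\beta=50$ anchor *defines* accuracy; if the morph is poor, a high-β
  projection is consistently wrong and $A$ cannot detect it — morph quality
  must be checked first.
* The all-source projection is $O(PN)$; dense matrices are chunked but a
  spatial index would be needed far beyond ~10⁵ nodes.
* One-element-thick layers only; multi-layer cortices would need a
  different pairing notion.
* The optimiser's greedy single-removal path cannot undo a removal and
  does not explore joint removals.
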