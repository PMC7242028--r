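---
title: "Methods: skeleton morphometry, synapse flow, NBLAST and template-space registration"
author: "skeletoolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skeleton morphometry, synapse flow, NBLAST and template-space registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skeletoolkit)
```

This vignette documents the models and procedures the package
implements, the conventions it fixes where several are defensible, and
what its synthetic-data tests do and do not demonstrate about real
data.

## The data model

A `neuron` is a rooted tree (or forest) of SWC-style nodes — integer
id, parent id (−1 at a root), 3D position, optional radius, structure
label — plus synaptic `connectors` (each a presynapse or postsynapse
attached to a node), named `tags` mapping strings to node sets, an
optional soma id, and a length-unit label. Validation enforces unique
positive ids, an acyclic parent relation, and referential integrity of
connectors, tags and soma. Two conventions matter downstream:

- **Endpoints are undirected degree-1 nodes**, so an unbranched root
  counts as an endpoint. Nothing in the source material fixes this
  either way; we declare it so counts are unambiguous.
- **Units are labels, never converted implicitly.** Skeletons from
  electron microscopy arrive in nanometres and light-level templates in
  micrometres; silent mixing is the classic failure, so any cross-unit
  operation is an error. Scaling happens only explicitly (e.g. the
  `unit_scale` argument of the compact-skeleton JSON reader).

Forests are allowed at the data level because real SWC files contain
multiple roots; operations that need a single tree (rerooting, Strahler
order, geodesics, flow centrality) check and say so. Node ids are
preserved verbatim everywhere except the explicit `canonicalise()`
(depth-first renumbering, children in id order).

A `neuronlist` couples an ordered, keyed set of neurons with exactly
one metadata row per member; `subset_list()` filters on the metadata and
`apply_to_all()` maps over members, defaulting to strict error
propagation (a lenient mode records missing values instead; the flag is
explicit because silent drop-outs bias population summaries).

## Morphometry

Cable length is the sum of parent-edge Euclidean lengths. Strahler
order is computed leaf-upward: leaves are order 1, a branch point takes
the maximum child order, incremented when that maximum is attained by
more than one child; unbranched runs inherit the downstream order, so
order is a per-branch quantity. The spine is the edge-weighted tree
diameter between endpoints; ties are broken toward the
lexicographically smallest sorted endpoint-id pair so results are
reproducible. Geodesic distances are along-skeleton shortest paths
(delegated to igraph; an independent Floyd–Warshall oracle checks them
in the tests).

Sholl profiles count, per radius, the skeleton–sphere crossings: edges
whose endpoint distances to the centre strictly straddle the radius,
plus nodes exactly on the sphere. Counting exact hits as crossings is a
deterministic convention; real coordinates hit it with probability
zero.

`resample()` re-parameterises each unbranched segment by arclength with
spacing `L / ceil(L / step)`, so spacing never exceeds `step` and
branch points and endpoints are preserved exactly. Interior vertices
are dropped: on a curved polyline the resampled chord sum is therefore
slightly shorter than the original cable (it cannot be longer), while
straight runs are preserved to machine precision. This is the standard
trade-off for uniform sampling; resample before any analysis that
assumes approximately equal point spacing (dotprops construction,
potential-synapse counting), not as a lossless storage step.

The backbone/twig split takes a boundary tag (e.g. nodes marking where
a neurite loses its microtubular backbone): tagged nodes are the last
backbone nodes and each tagged node's strict descendants form one twig.
Nested tags resolve to the most proximal one, which is logged rather
than raised, because nested annotations occur in practice and the
proximal tag dominates anatomically.

## Synapse-flow centrality and the compartment split

With the tree rooted at the soma, each node *v* splits the synapses
into those attached within its subtree (*v* inclusive) and the rest.
Writing `I` for postsynapse (input) counts and `O` for presynapse
(output) counts, with subscripts *d* (distal, in the subtree) and *p*
(proximal, the remainder):

- centrifugal(v) = I_p(v) · O_d(v)
- centripetal(v) = I_d(v) · O_p(v)
- total(v) = centrifugal + centripetal

This equals the number of input→output paths forced through *v*. A
synapse attached at *v* counts as distal; the consequence — the
synapse-bearing node itself may carry zero flow — is accepted because
it makes the subtree formula exact.

The split: the neuron divides at the maximum-total-flow node that is
geodesically closest to the root (ties to the smallest id). The split
node's subtree and the remainder are the two arbour compartments; the
one with the higher presynapse fraction is the axon (tie: higher
absolute presynapse count; a tie on both raises an "unpolarised"
error). The maximal connected run of zero-flow, synapse-free nodes
containing the root is relabelled the cell-body fibre. All nodes
attaining the maximal flow are reported as the flow plateau — the
intervening cable between the compartments (the insect "primary
dendrite"). We deliberately flag the plateau instead of carving it into
a fourth labelled compartment: no boundary rule for it is given in the
method's description, and flagging preserves the information without
inventing one.

The polarity generator plants this anatomy explicitly: a synapse-free
fibre, a postsynapse-rich dendritic arbour and a presynapse-rich axonal
arbour joined by short linking neurites sampled at the skeleton's
internode spacing. The linking cable *is* the flow plateau and is
planted as its own `"intervening"` class: whichever side of it the
split lands on is anatomically defensible, so recovery metrics score
only the unambiguous cable. At synapse purity 0.95 the split recovers
about 98% of that cable pooled over 20 seeds. Recovery is assessed on
pooled cable because it fluctuates per draw: when a sparse proximal
stretch of an arbour happens to carry only noise synapses, the flow
maximum legitimately sits below it — the split is optimal for the
realized synapses even though it disagrees with the plant there.

## NBLAST

`make_dotprops()` converts a (typically resampled) skeleton into a
vector cloud: each point carries the dominant eigenvector of the
covariance of its *k* nearest points (self inclusive, default k = 5)
and a colinearity weight α = (λ₁ − λ₂)/(λ₁ + λ₂ + λ₃). Tangent sign is
meaningless by construction; all scoring uses the absolute dot
product.

A query scores against a target by matching each query point to its
nearest target point and summing f(dᵢ, aᵢ). Two scorers are supported:

- **parametric**: f(d, a) = a · exp(−d²/(2σ²)), default σ = 3 in query
  units. The original method's trained scoring matrices are corpus
  products that cannot be rederived here, so a transparent parametric
  form is the default; σ, like everything else, is a visible parameter.
- **matrix**: an empirical log-score grid over (distance, |dot|) bins,
  read from a documented TSV layout; out-of-range values clamp to the
  edge bins.

Normalisations: `raw`, `self` (divide by the query's self-score, so
identical clouds score 1) and `mean` (mean of the two self-normalised
directions, symmetric with unit diagonal — the form used for
clustering). α-weighting of query points is available behind a flag and
off by default. Clustering converts a symmetric table to the distance
1 − score clipped to [0, 2] and applies Ward linkage (`ward.D2`);
linkage is a parameter, and the merge tree exports as Newick text.
Principal-axes alignment puts the soma (else centroid) at the origin
and rotates onto the variance-ordered principal frame, flipping each
axis so its coordinate skewness is non-negative; near-degenerate frames
(spherical clouds) fall back to the identity rotation with a warning.

## Registration and template spaces

Affine transforms are fitted by least squares on ≥4 non-coplanar
landmark pairs. Thin-plate splines use the 3D biharmonic kernel
U(r) = r with an affine part; λ = 0 (the default) interpolates every
landmark exactly, and λ > 0 trades fidelity for smoothness. The kernel
choice is the standard one for 3D landmark warps; nothing in the source
material fixes it.

Numerical inversion solves t(y) = x per point by damped Newton with a
central-difference Jacobian, started at y = x (default tolerance 1e−6
units, 100 iterations); affine transforms short-circuit to the
closed-form inverse and flips to themselves. Non-convergence is an
error naming the point — boundary points of strongly non-linear warps
legitimately fail to invert and silence would hide it.

A `template_space` names a coordinate system with a unit and bounding
box. Mirroring flips the medio-lateral coordinate within the box
(x → lo + hi − x; the axis is per-space configurable, defaulting to x
as in the fly templates), then applies the space's non-rigid
mirror-correction transform when one is registered — a plain flip is
insufficient for real brains, whose hemispheres differ by small
displacements. Segment-wise symmetry scoring mirrors the neuron and
scores each unbranched segment (tangents taken from the whole-neuron
cloud, so branch-point geometry stays comparable) against the whole
mirrored neuron with self-normalised NBLAST: symmetric cable scores
near 1, unilateral cable near 0.

A `bridging_registry` is a directed graph of spaces connected by
transforms. Routing uses shortest paths with weight 1 for native edges
and 1.1 for traversing an invertible edge backwards via numerical
inversion, so explicitly constructed registrations are preferred over
numeric inverses whenever both exist. Transforms along the path are
composed in order; the path is logged and attached to the result.

## Volumetrics

Mesh volume is the signed-tetrahedron sum |Σ det(v₁,v₂,v₃)|/6, valid
only for closed, consistently oriented regions, which are checked
(every directed edge used exactly once, every undirected edge twice).
Point membership uses ray parity with a fixed ray; hits that graze an
edge or vertex are retried with deterministically jittered rays, and
points on the surface count as inside (a stated convention). Skeleton
pruning against a volume is vertex-based — nodes on the losing side are
removed and the remainder re-validated as a forest — so node ids stay
stable; resample first if boundary-crossing cable error matters.

Convex hulls use an incremental visibility algorithm; alpha shapes
keep the Delaunay tetrahedra with circumradius below α (α → ∞ recovers
the hull) and take the boundary faces of that union, oriented outward.
The Delaunay tetrahedralisation is a Bowyer–Watson implementation with
a deterministic relative 1e−8 jitter to break cospherical
degeneracies and a far super-tetrahedron so near-hull slivers are not
lost; both structures are built in R because no installed package
provides 3D hulls or tetrahedralisations, and they are validated
against closed forms (cube, tetrahedron, icosphere) and containment
properties in the tests. These implementations target the point-cloud
sizes of skeleton analysis (hundreds of points), not large meshes.

The overlap score of A against B is Σ exp(−d(a,B)²/(2δ²)) over points
of A (nearest-neighbour distance d), deliberately asymmetric.
Potential-synapse counting resamples both skeletons to edge length
≤ s/2 and, over edge pairs with midpoint distance ≤ s, reports the raw
pair count and Σ ℓᵢℓⱼ sin θᵢⱼ. Both are reported unnormalised: the
original formulation's normalising constants are not public, so none
are invented and users calibrate against their own data.

## Synthetic data: what the tests show

All fixtures are generated by seeded, pure functions (the caller's RNG
state is never touched): random stepwise-growth trees, polarity-planted
neurons, jittered morphological families, bilaterally symmetric
neurons, and registration scenarios whose landmark sets are exactly
consistent with a planted transform (for warps, the landmarks are the
planted spline's own control points, so refitting recovers the map
identically on held-out points).

Problem sizes are chosen so the full suite runs in well under a minute
per module on one CPU: trees of 30–200 nodes, 25–50 oracle
comparisons, families of 2 × 10 neurons of ~50 nodes, 10⁴-point
membership checks, 5×5×5 inversion grids. These sizes are where the
brute-force oracles (exhaustive subtree recounts, Floyd–Warshall,
all-pairs nearest-neighbour scans) remain cheap, which is what makes
the dual-route checks meaningful.

What passing does and does not show: the generators reproduce the
*statistical structure* each algorithm assumes — polarity segregation,
within/between-family separation, bilateral symmetry, smooth warps —
not realistic neuronal morphology. Real reconstructions add tracing
errors, broken arbours, soma-less fragments, non-smooth deformations
between specimens, and empirically trained scoring matrices; results
here demonstrate correctness of the computations, not biological
performance on any particular corpus. In the same spirit, quantities
published for specific brain atlases (registration residuals,
hemisphere-asymmetry statistics) depend on those corpora and
registrations and are out of scope; the acceptance script instead
reports the package's own oracle agreements, recovery rates and closed
forms.

## Numerical choices, edge cases, limitations

- OBJ faces are stored 1-based internally (the R indexing convention)
  and converted at the file boundary; SWC's missing radii are written
  as 0 with a header flag and restored on read.
- Scoring-matrix lookups clamp out-of-range distances and dot products
  to edge bins; degenerate (coincident-point) neighbourhoods in
  dotprops construction are errors, not NaNs.
- The spine tie-break, Sholl on-sphere rule, flip-axis default and
  plateau flagging are all declared conventions chosen for determinism;
  each is overridable where it is a parameter.
- Transforms are assumed locally invertible where inversion is
  requested; the inverter reports the failing point otherwise.
- The hull/Delaunay code trades asymptotic performance for clarity and
  is not intended for meshes or clouds beyond a few thousand points.
- No voxel-image registration or intensity-based registration
  construction is provided; the `transform` interface is the extension
  point for wrapping external deformation engines.
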