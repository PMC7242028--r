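# skeletoolkit

Analysis toolbox for neuron skeletons with synapse annotations, written
for computational neuroanatomists working with tracings from light or
electron microscopy. A neuron is modelled as a rooted tree of 3D nodes
(the SWC convention: each node has an id, a position, a radius and a
parent), optionally carrying synaptic connectors (presynapses and
postsynapses), string tags and a soma marker. On top of this data model
the package provides:

- **I/O** for the formats such data travels in: SWC skeletons, offline
  CATMAID-style compact-skeleton JSON (nodes + connectors + tags),
  Wavefront OBJ neuropil meshes, landmark-pair CSV, NBLAST
  scoring-matrix TSV, and a bridging-registry JSON naming template
  spaces and transform files.
- **Morphometry**: summary statistics (node/branch/endpoint counts,
  total cable length), Strahler order and Strahler-based pruning, the
  longest path ("spine"), within-skeleton geodesic distances, Sholl
  profiles, arclength resampling, and splitting a skeleton into
  microtubular backbone versus twigs at tagged nodes.
- **Synapse-flow polarity**: for each node *v*, with inputs *I* and
  outputs *O* partitioned into the subtree of *v* (subscript *d*) and
  the remainder (subscript *p*), centrifugal flow is
  *I_p(v)·O_d(v)*, centripetal flow is *I_d(v)·O_p(v)*, and the neuron
  is split into axon, dendrite and cell-body fibre at the most proximal
  node of maximal total flow.
- **NBLAST similarity**: skeletons become vector clouds (each point
  carries the dominant principal direction of its *k* nearest
  neighbours and a colinearity weight α); a query scores against a
  target by summing *f(d_i, |u_i·v_i|)* over nearest-neighbour matches,
  with either the parametric scorer *f(d,a) = a·exp(−d²/2σ²)* (default
  σ = 3) or an empirical scoring matrix. Score tables can be
  self-normalised or symmetrised, hierarchically clustered (Ward) and
  exported as Newick dendrograms; clouds can be aligned by principal
  axes.
- **Registration**: least-squares affine and 3D thin-plate-spline
  (kernel U(r) = r) transforms fitted to landmark pairs, axis flips,
  sequences, damped-Newton numerical inversion, mirroring across a
  template's midplane with an optional non-rigid correction, and a
  bridging graph that routes data between named template spaces by
  composing (and where needed inverting) registered transforms.
- **Volumetrics**: closed-mesh volumes, ray-parity point-in-mesh tests,
  pruning a skeleton to the cable inside/outside a volume, convex hulls
  and alpha shapes of point clouds, proximity overlap scores, and
  potential-synapse counts weighted by approach angle.
- **Synthetic data**: deterministic generators for random tree
  skeletons, polarity-planted neurons with ground-truth compartments,
  morphological families, bilaterally symmetric neurons and
  registration scenarios with planted transforms — everything the test
  suite needs, generated offline.

## Worked example

```r
library(skeletoolkit)

# a 4-node Y-shaped toy skeleton shipped with the package
n <- read_swc(system.file("extdata", "y4.swc", package = "skeletoolkit"))
summary_stats(n)
#> nodes 4 | branch points 1 | endpoints 3 | cable 3 | components 1 | pre 0 | post 0
strahler_order(n)
#> 1 2 3 4
#> 2 2 1 1

# axon/dendrite/cell-body-fibre split of a synapse-annotated skeleton
pol <- read_catmaid_skeleton_json(
  system.file("extdata", "polarity_chain.synthetic.json", package = "skeletoolkit"))
split_axon_dendrite(pol)
#> <flow_result> max flow 1 at node(s) 3,4,5
#>   compartments: axon=3 cell_body_fiber=1 dendrite=1

# NBLAST + clustering recovers two planted morphological families
fam <- gen_morph_families(n_families = 2, n_per_family = 5, seed = 1)
cl <- cluster_scores(nblast_all_by_all(fam), k = 2)
table(cluster = cl$labels, family = nl_metadata(fam)$family)
#>        family
#> cluster 1 2
#>       1 5 0
#>       2 0 5
```

The summary says the Y-neuron has one branch point, three endpoints and
3 µm of cable; its two leaf branches are Strahler order 1 and merge into
an order-2 trunk. The split labels the proximal synapse-free node as
cell-body fibre, the postsynaptic stretch as dendrite and the
presynaptic side beyond the maximum-flow point as axon. The clustering
table shows a perfect 2-family partition.

A thin command-line wrapper over the same functions is installed at
`system.file("exec", "skeletoolkit", package = "skeletoolkit")` with
subcommands `summary`, `convert`, `sholl`, `prune`, `split`, `nblast`,
`cluster`, `inside`, `prune-volume`, `xform`, `mirror` and `gen`.

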