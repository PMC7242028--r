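#!/usr/bin/env Rscript
# Regenerates the small plain-text fixtures under inst/extdata/.
# Run from the package root: Rscript tools/make_fixtures.R

library(skeletoolkit)

out <- file.path("inst", "extdata")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# Y-shaped 4-node toy neuron (1 branch point, cable 3)
y4 <- build_neuron(data.frame(id = 1:4, parent_id = c(-1, 1, 2, 2),
                              x = c(0, 0, 0, 1), y = c(0, 0, 1, 0),
                              z = c(0, 1, 1, 1), radius = 1))
write_swc(y4, file.path(out, "y4.swc"))

# straight 11-node chain, unit spacing (cable 10)
chain <- build_neuron(data.frame(id = 1:11, parent_id = c(-1, 1:10),
                                 x = 0, y = 0, z = 0:10, radius = 0.5))
write_swc(chain, file.path(out, "chain11.swc"))

# unit cube as OBJ
cube <- fit_bounding_volume(as.matrix(expand.grid(0:1, 0:1, 0:1)),
                            method = "convex_hull")
write_obj_mesh(cube, file.path(out, "cube.obj"))

# synthetic compact-skeleton JSON: worked polarity example
# (chain rooted at the soma, postsynapse at node 2, presynapse at node 5)
conn <- data.frame(connector_id = 1:2, node_id = c(2L, 5L),
                   polarity = c("postsynapse", "presynapse"),
                   x = 0, y = 0, z = c(1, 4))
pol <- build_neuron(build_neuron(data.frame(
  id = 1:5, parent_id = c(-1, 1:4), x = 0, y = 0, z = 0:4))$nodes,
  connectors = conn, tags = list(soma = 1L))
write_catmaid_skeleton_json(pol, file.path(out, "polarity_chain.synthetic.json"))

# landmark pairs consistent with a planted affine map
src <- as.matrix(expand.grid(c(0, 50, 100), c(0, 40, 80), c(0, 30, 60)))
t0 <- affine_transform(cbind(rbind(c(1.05, 0.02, 0),
                                   c(-0.02, 0.98, 0.01),
                                   c(0, 0.03, 1.1)), c(2, -1, 3)))
write_landmarks_csv(landmark_pairs(src, apply_transform(t0, src)),
                    file.path(out, "affine_landmarks.synthetic.csv"))

# small scoring matrix in the TSV layout
sm <- scoring_matrix(c(0, 0.75, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 20, 25, 30, 40, 500),
                     seq(0, 1, length.out = 11),
                     outer(seq(5, -9, length.out = 21),
                           seq(-2, 2, length.out = 10),
                           function(a, b) round(a + b, 3)))
write_scoring_matrix(sm, file.path(out, "scoring_matrix_demo.synthetic.tsv"))

# two-space bridging registry wired by the planted affine
A <- template_space("A", bbox_lo = c(0, 0, 0), bbox_hi = c(100, 80, 60))
B <- template_space("B", bbox_lo = c(-10, -10, -10), bbox_hi = c(120, 95, 80))
reg <- bridging_registry(list(A, B),
                         list(list(from = "A", to = "B", transform = t0,
                                   invertible = TRUE)))
write_registry_json(reg, file.path(out, "registry_demo.json"))

cat("fixtures written to", out, "\n")
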