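test_that("mesh volumes match closed forms and scale correctly", {
  cube <- cube_mesh()
  expect_equal(mesh_volume(cube), 1)
  tet <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                 rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
  expect_equal(mesh_volume(tet), 1 / 6)
  sph <- icosphere_mesh(3)
  expect_lt(abs(mesh_volume(sph) - 4 * pi / 3) / (4 * pi / 3), 0.01)
  # rigid-motion invariance and cubic scaling
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- apply_transform(affine_transform(cbind(R, c(3, -1, 2))), cube)
  expect_equal(mesh_volume(moved), 1, tolerance = 1e-9)
  scaled <- apply_transform(affine_transform(cbind(diag(3) * 2.5, 0)), cube)
  expect_equal(mesh_volume(scaled), 2.5^3, tolerance = 1e-9)
  # open mesh rejected
  open_mesh <- trimesh(tet$vertices, tet$faces[1:3, ])
  expect_error(mesh_volume(open_mesh), "open mesh")
})

test_that("point-in-mesh agrees with analytic membership", {
  cube <- cube_mesh()
  expect_equal(points_inside(rbind(c(0.5, 0.5, 0.5), c(1.5, 0.5, 0.5)), cube),
               c(TRUE, FALSE))
  # point exactly on a face counts as inside
  expect_true(points_inside(rbind(c(1, 0.5, 0.5)), cube))
  sph <- icosphere_mesh(3)
  # exclude the faceting shell: faces lie between the inscribed distance
  # and the unit circumradius
  v <- sph$vertices[t(sph$faces), ]
  dmin <- min(sqrt(rowSums(
    ((v[seq(1, nrow(v), 3), ] + v[seq(2, nrow(v), 3), ] +
        v[seq(3, nrow(v), 3), ]) / 3)^2)))
  set.seed(9)
  pts <- matrix(runif(3 * 6000, -1.3, 1.3), ncol = 3)
  r <- sqrt(rowSums(pts^2))
  keep <- r < dmin - 1e-9 | r > 1 + 1e-9
  pts <- pts[keep, ][1:4000, ]
  r <- sqrt(rowSums(pts^2))
  expect_equal(points_inside(pts, sph), r < dmin)
})

test_that("in-volume pruning keeps the requested side and partitions nodes", {
  cube <- cube_mesh()
  ch <- build_neuron(data.frame(id = 1:9, parent_id = c(-1, 1:8),
                                x = seq(-0.5, 1.5, 0.25), y = 0.5, z = 0.5))
  ch$unit <- cube$unit
  inside <- prune_in_volume(ch, cube, "inside")
  expect_equal(nrow(inside$nodes), 5L)
  expect_equal(summary_stats(inside)$cable_length, 1)
  outside <- prune_in_volume(ch, cube, "outside")
  expect_setequal(c(inside$nodes$id, outside$nodes$id), ch$nodes$id)
  whole <- build_neuron(data.frame(id = 1:3, parent_id = c(-1, 1, 2),
                                   x = c(0.2, 0.5, 0.8), y = 0.5, z = 0.5))
  whole$unit <- cube$unit
  expect_identical(prune_in_volume(whole, cube, "inside")$nodes, whole$nodes)
  expect_error(prune_in_volume(whole, cube, "outside"), "empty result")
})

test_that("bounding volumes: hulls contain the cloud, alpha shapes split clusters", {
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  hull <- fit_bounding_volume(corners, "convex_hull")
  expect_equal(mesh_volume(hull), 1)
  expect_equal(length(unique(as.vector(hull$faces))), 8L)
  set.seed(10)
  cloud <- matrix(runif(300), 100, 3)
  h2 <- fit_bounding_volume(cloud, "convex_hull")
  expect_true(all(points_inside(cloud, h2)))
  expect_error(fit_bounding_volume(cbind(runif(10), runif(10), 0), "convex_hull"),
               "degenerate")
  # two well-separated blobs: small alpha gives two shells, alpha -> Inf the hull
  blob <- rbind(matrix(runif(60), 20, 3), matrix(runif(60), 20, 3) + 10)
  a_small <- fit_bounding_volume(blob, "alpha_shape", alpha = 3)
  expect_equal(attr(a_small, "n_components"), 2L)
  a_inf <- fit_bounding_volume(blob, "alpha_shape", alpha = Inf)
  expect_equal(attr(a_inf, "n_components"), 1L)
  hull_blob <- fit_bounding_volume(blob, "convex_hull")
  expect_equal(mesh_volume(a_inf), mesh_volume(hull_blob), tolerance = 1e-6)
})

test_that("overlap score has its closed forms and decays with distance", {
  set.seed(11)
  A <- matrix(runif(60), 20, 3)
  expect_equal(overlap_score(A, A, delta = 1), 20)
  p1 <- rbind(c(0, 0, 0))
  p2 <- rbind(c(1, 0, 0))
  expect_equal(overlap_score(p1, p2, delta = 1), exp(-0.5), tolerance = 1e-12)
  expect_lt(overlap_score(A, A + 100, delta = 1), 1e-12)
  offs <- seq(0, 5, 1)
  sc <- vapply(offs, function(o) overlap_score(A, A + cbind(o, 0, 0)[rep(1, 20), ],
                                               delta = 1), numeric(1))
  expect_true(all(diff(sc) <= 1e-9))
})

test_that("potential synapses weight close pairs by approach angle", {
  seg <- function(p1, p2) {
    build_neuron(data.frame(id = 1:2, parent_id = c(-1, 1),
                            x = c(p1[1], p2[1]), y = c(p1[2], p2[2]),
                            z = c(p1[3], p2[3])))
  }
  perp <- potential_synapses(seg(c(-0.5, 0, 0), c(0.5, 0, 0)),
                             seg(c(0, -0.5, 0), c(0, 0.5, 0)), s = 1)
  expect_equal(perp$angle_weighted_sum, 1, tolerance = 1e-12)
  par <- potential_synapses(seg(c(-0.5, 0, 0), c(0.5, 0, 0)),
                            seg(c(-0.5, 0.2, 0), c(0.5, 0.2, 0)), s = 1)
  expect_equal(par$angle_weighted_sum, 0, tolerance = 1e-12)
  far <- potential_synapses(seg(c(-0.5, 0, 0), c(0.5, 0, 0)),
                            seg(c(9.5, 0, 0), c(10.5, 0, 0)), s = 1)
  expect_equal(far$close_pair_count, 0L)
  expect_equal(far$angle_weighted_sum, 0)
  # symmetry in (A, B)
  a <- gen_tree_neuron(30, seed = 12)
  b <- gen_tree_neuron(30, seed = 13)
  ab <- potential_synapses(a, b, s = 2)
  ba <- potential_synapses(b, a, s = 2)
  expect_equal(ab$close_pair_count, ba$close_pair_count)
  expect_equal(ab$angle_weighted_sum, ba$angle_weighted_sum, tolerance = 1e-9)
})
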