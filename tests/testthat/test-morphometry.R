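test_that("summary statistics match hand-derived values", {
  s <- summary_stats(y4_neuron())
  expect_equal(s$n_nodes, 4L)
  expect_equal(s$n_branch_points, 1L)
  expect_equal(s$n_endpoints, 3L)
  expect_equal(s$cable_length, 3)

  s1 <- summary_stats(build_neuron(data.frame(id = 1, parent_id = -1,
                                              x = 0, y = 0, z = 0)))
  expect_equal(s1$n_nodes, 1L)
  expect_equal(s1$n_branch_points, 0L)
  expect_equal(s1$n_endpoints, 1L)
  expect_equal(s1$cable_length, 0)

  s11 <- summary_stats(chain_neuron(11))
  expect_equal(s11$cable_length, 10)
  expect_equal(s11$n_endpoints, 2L)
})

test_that("Strahler order follows the leaf-upward merging rule", {
  expect_true(all(strahler_order(chain_neuron(7)) == 1L))
  expect_equal(unname(strahler_order(y4_neuron())), c(2L, 2L, 1L, 1L))
  # complete binary tree of depth 4: root order = 4 (recursive oracle)
  strahler_oracle <- function(nodes, id) {
    kids <- nodes$id[nodes$parent_id == id]
    if (length(kids) == 0) return(1L)
    ko <- vapply(kids, function(k) strahler_oracle(nodes, k), integer(1))
    m <- max(ko)
    if (sum(ko == m) > 1L) m + 1L else m
  }
  bt <- binary_tree_neuron(4)
  so <- strahler_order(bt)
  expect_equal(so[["1"]], 4L)
  expect_equal(unname(so[as.character(bt$nodes$id)]),
               vapply(bt$nodes$id, function(i) strahler_oracle(bt$nodes, i),
                      integer(1)))
})

test_that("Strahler pruning removes low orders and conserves cable", {
  pruned <- prune_by_strahler(y4_neuron(), min_order = 2)
  expect_equal(sort(pruned$nodes$id), c(1L, 2L))
  expect_equal(summary_stats(pruned)$cable_length, 1)
  expect_identical(prune_by_strahler(y4_neuron(), min_order = 1)$nodes,
                   y4_neuron()$nodes)
  expect_error(prune_by_strahler(chain_neuron(5), min_order = 2), "empty")
  # cable conservation: kept + removed = total
  for (seed in 1:5) {
    n <- build_neuron(random_tree_nodes(60, seed + 40))
    total <- summary_stats(n)$cable_length
    ord <- strahler_order(n)
    if (max(ord) < 2) next
    kept <- summary_stats(prune_by_strahler(n, 2))$cable_length
    # removed cable: edges whose child node has order 1
    idx <- match(n$nodes$parent_id, n$nodes$id)
    ok <- which(!is.na(idx))
    xyz <- as.matrix(n$nodes[, c("x", "y", "z")])
    w <- sqrt(rowSums((xyz[ok, ] - xyz[idx[ok], ])^2))
    removed <- sum(w[ord[as.character(n$nodes$id[ok])] == 1L])
    expect_equal(kept + removed, total, tolerance = 1e-12)
  }
})

test_that("spine is the edge-weighted diameter with deterministic ties", {
  ch <- chain_neuron(11)
  sp <- spine(ch)
  expect_equal(sp$path, 1:11)
  expect_equal(sp$length, 10)
  spy <- spine(y4_neuron())
  expect_equal(spy$length, 2)
  expect_equal(spy$path, c(1L, 2L, 3L))  # smallest sorted endpoint pair (1,3)
  single <- build_neuron(data.frame(id = 1, parent_id = -1, x = 0, y = 0, z = 0))
  expect_equal(spine(single), list(path = 1L, length = 0))
  # spine <= cable, equality iff unbranched
  for (seed in 1:5) {
    n <- build_neuron(random_tree_nodes(50, seed + 60))
    s <- summary_stats(n)
    expect_lte(spine(n)$length, s$cable_length + 1e-12)
    if (s$n_branch_points == 0L) {
      expect_equal(spine(n)$length, s$cable_length)
    }
  }
  expect_equal(spine(chain_neuron(9, 0.5))$length,
               summary_stats(chain_neuron(9, 0.5))$cable_length)
})

test_that("geodesic distances equal a Floyd-Warshall oracle", {
  expect_equal(geodesic_distances(y4_neuron(), 3, 4)[1, 1], 2)
  expect_equal(geodesic_distances(y4_neuron(), 1, 1)[1, 1], 0)
  expect_error(geodesic_distances(y4_neuron(), 1, 99), "unknown node")
  for (seed in 1:6) {
    n <- build_neuron(random_tree_nodes(100, seed + 80))
    expect_equal(geodesic_distances(n), fw_geodesics(n), tolerance = 1e-10)
  }
})

test_that("Sholl crossings count sphere straddles", {
  ch <- chain_neuron(11)  # straight along z from 0 to 10
  pr <- sholl_analysis(ch, center = c(0, 0, 0), radii = seq(0.5, 9.5, 1))
  expect_true(all(pr$crossings == 1L))
  expect_equal(sholl_analysis(ch, c(0, 0, 0), 10.5)$crossings, 0L)
  expect_error(sholl_analysis(ch, c(0, 0, 0), c(2, 1)), "ascending")
  # star with k arms: crossings = k for every radius inside the arms
  st <- star_neuron(k = 5, arm_length = 5, step = 0.5)
  pr2 <- sholl_analysis(st, center = c(0, 0, 0), radii = c(0.7, 2.2, 4.4))
  expect_true(all(pr2$crossings == 5L))
  # Y-neuron: both leaves beyond the branch point -> 2 crossings out there
  y <- y4_neuron()
  expect_equal(sholl_analysis(y, c(0, 0, 0), sqrt(2) * 0.999)$crossings, 2L)
})

test_that("resampling keeps break points and straight-run cable", {
  ch3 <- build_neuron(data.frame(id = 1:3, parent_id = c(-1, 1, 2),
                                 x = 0, y = 0, z = c(0, 5, 10)))
  rs <- resample(ch3, 1)
  expect_equal(nrow(rs$nodes), 11L)
  expect_equal(summary_stats(rs)$cable_length, 10)
  y <- resample(y4_neuron(), 0.5)
  xyz <- as.matrix(y$nodes[, c("x", "y", "z")])
  expect_true(any(apply(xyz, 1, function(p) all(p == c(0, 0, 1)))))  # branch kept
  # step larger than segments: only root/branch/end nodes remain
  coarse <- resample(y4_neuron(), 10)
  expect_equal(nrow(coarse$nodes), 4L)
  # per-segment spacing <= step
  rs2 <- resample(build_neuron(random_tree_nodes(40, 7)), 0.8)
  idx <- match(rs2$nodes$parent_id, rs2$nodes$id)
  ok <- which(!is.na(idx))
  xyz2 <- as.matrix(rs2$nodes[, c("x", "y", "z")])
  expect_lte(max(sqrt(rowSums((xyz2[ok, ] - xyz2[idx[ok], ])^2))), 0.8 + 1e-9)
})

test_that("backbone/twig splitting honours boundary tags", {
  ch <- chain_neuron(5)
  ch$tags <- list(mt_end = 3L)
  out <- split_backbone_twigs(ch, "mt_end")
  expect_equal(sort(out$backbone$nodes$id), 1:3)
  expect_length(out$twigs, 1L)
  expect_equal(sort(out$twigs[[1]]$nodes$id), 4:5)
  # no tagged nodes
  ch2 <- chain_neuron(5); ch2$tags <- list(mt_end = integer(0))
  out2 <- split_backbone_twigs(ch2, "mt_end")
  expect_equal(nrow(out2$backbone$nodes), 5L)
  expect_length(out2$twigs, 0L)
  # tag at root
  ch3 <- chain_neuron(4); ch3$tags <- list(mt_end = 1L)
  out3 <- split_backbone_twigs(ch3, "mt_end")
  expect_equal(out3$backbone$nodes$id, 1L)
  expect_equal(sort(out3$twigs[[1]]$nodes$id), 2:4)
  # nested tags resolve to the most proximal
  ch4 <- chain_neuron(6); ch4$tags <- list(mt_end = c(2L, 4L))
  out4 <- suppressMessages(split_backbone_twigs(ch4, "mt_end"))
  expect_equal(sort(out4$backbone$nodes$id), 1:2)
  expect_length(out4$twigs, 1L)
  expect_error(split_backbone_twigs(chain_neuron(3), "absent"), "tag not present")
})
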