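test_that("build_neuron validates the skeleton data model", {
  y4 <- y4_neuron()
  expect_s3_class(y4, "neuron")
  expect_equal(nrow(y4$nodes), 4L)
  expect_equal(y4$meta$n_components, 1L)

  single <- build_neuron(data.frame(id = 1, parent_id = -1, x = 0, y = 0, z = 0))
  expect_equal(nrow(single$nodes), 1L)
  expect_equal(sum(single$nodes$parent_id != -1), 0L)

  expect_error(build_neuron(data.frame(id = c(1, 2), parent_id = c(2, 1),
                                       x = 0, y = 0, z = 0)), "cycle")
  expect_error(build_neuron(data.frame(id = c(1, 1), parent_id = c(-1, 1),
                                       x = 0, y = 0, z = 0)), "duplicate")
  expect_error(build_neuron(data.frame(id = 1, parent_id = -1, x = 0, y = 0, z = 0),
                            connectors = data.frame(connector_id = 1, node_id = 9,
                                                    polarity = "presynapse",
                                                    x = 0, y = 0, z = 0)),
               "unknown node")
  expect_error(build_neuron(data.frame(id = 1, parent_id = -1, x = 0, y = 0, z = 0),
                            tags = list(soma = 9L)), "unknown node")
  # dangling parent: error by default, promotable to root
  dang <- data.frame(id = 1:2, parent_id = c(-1, 99), x = 0, y = 0, z = 0:1)
  expect_error(build_neuron(dang), "missing node")
  fixed <- build_neuron(dang, on_missing_parent = "root")
  expect_equal(fixed$meta$n_components, 2L)
  expect_equal(fixed$meta$promoted_roots, 2L)
})

test_that("reroot reverses the path but preserves geometry", {
  ch <- chain_neuron(5)
  r5 <- reroot(ch, 5)
  expect_equal(r5$nodes$parent_id, c(2L, 3L, 4L, 5L, -1L))
  # undirected edge multiset identical
  edge_set <- function(n) {
    idx <- n$nodes$parent_id != -1
    e <- cbind(n$nodes$id[idx], n$nodes$parent_id[idx])
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_identical(edge_set(ch), edge_set(r5))
  expect_identical(reroot(ch, 1)$nodes, ch$nodes)
  expect_error(reroot(ch, 99), "unknown node")

  # geodesic distances invariant under rerooting, vs brute-force oracle
  for (seed in 1:5) {
    n <- build_neuron(random_tree_nodes(50, seed))
    target <- sample(n$nodes$id, 1)
    rr <- reroot(n, target)
    expect_identical(edge_set(n), edge_set(rr))
    expect_equal(geodesic_distances(rr), fw_geodesics(n), tolerance = 1e-12)
  }
})

test_that("subset_list filters by metadata and composes", {
  nl <- neuronlist(list(a = chain_neuron(3), b = chain_neuron(4), c = chain_neuron(5)),
                   data.frame(key = c("a", "b", "c"), cable = c(100, 600, 700)))
  kept <- subset_list(nl, cable > 500)
  expect_equal(names(kept), c("b", "c"))
  expect_equal(nl_metadata(kept)$cable, c(600, 700))
  expect_equal(names(subset_list(nl, TRUE)), names(nl))
  empty <- subset_list(nl, FALSE)
  expect_length(empty, 0L)
  expect_equal(nrow(nl_metadata(empty)), 0L)
  expect_error(subset_list(nl, no_such_column > 1), "missing metadata column")
  # composition p then q == p & q
  ab <- subset_list(subset_list(nl, cable > 150), cable < 650)
  both <- subset_list(nl, cable > 150 & cable < 650)
  expect_identical(names(ab), names(both))
})

test_that("apply_to_all maps with keys and strict/lenient error modes", {
  nl <- neuronlist(list(a = y4_neuron(), b = chain_neuron(11)))
  idl <- apply_to_all(nl, identity)
  expect_s3_class(idl, "neuronlist")
  expect_identical(names(idl), names(nl))
  cables <- apply_to_all(nl, function(n) summary_stats(n)$cable_length)
  expect_equal(unname(cables), c(3, 10))
  expect_named(cables, c("a", "b"))
  boom <- function(n) if (nrow(n$nodes) > 5) stop("too big") else n
  expect_error(apply_to_all(nl, boom, strict = TRUE), "'b'")
  res <- suppressMessages(apply_to_all(nl, boom, strict = FALSE))
  expect_identical(names(res), "a")
})

test_that("segment decomposition partitions edges between break points", {
  segs <- segment_decomposition(y4_neuron())$segments
  expect_equal(segs, list(c(1L, 2L), c(2L, 3L), c(2L, 4L)))
  expect_equal(segment_decomposition(chain_neuron(5))$segments, list(1:5))
  bt <- segment_decomposition(binary_tree_neuron(3))$segments
  expect_length(bt, 6L)  # complete binary tree, 3 levels: 2^d - 2 segments
  # invariant: sum over segments of (len - 1) = nodes - components
  for (seed in 1:5) {
    n <- build_neuron(random_tree_nodes(40, seed + 20))
    segs <- segment_decomposition(n)$segments
    expect_equal(sum(lengths(segs) - 1L), nrow(n$nodes) - 1L)
    # every edge in exactly one segment
    edges <- unlist(lapply(segs, function(p) {
      paste(pmin(p[-length(p)], p[-1]), pmax(p[-length(p)], p[-1]))
    }))
    expect_equal(anyDuplicated(edges), 0L)
    expect_length(edges, nrow(n$nodes) - 1L)
  }
})

test_that("canonicalise renumbers depth-first and preserves structure", {
  n <- build_neuron(random_tree_nodes(30, 3))
  cn <- canonicalise(n)
  expect_equal(sort(cn$nodes$id), 1:30)
  expect_equal(summary_stats(cn)$cable_length, summary_stats(n)$cable_length)
  expect_equal(summary_stats(cn)$n_branch_points, summary_stats(n)$n_branch_points)
})
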