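test_that("affine fitting recovers a planted map exactly", {
  set.seed(2)
  s <- matrix(runif(30, 0, 10), 10, 3)
  t0 <- known_affine()
  lm <- landmark_pairs(s, apply_transform(t0, s))
  fit <- fit_affine(lm)
  expect_lt(max(abs(fit$matrix - t0$matrix)), 1e-9)
  # identity pairs give the identity matrix
  idfit <- fit_affine(landmark_pairs(s, s))
  expect_lt(max(abs(idfit$matrix - cbind(diag(3), 0))), 1e-9)
  expect_error(fit_affine(landmark_pairs(s[1:3, ], s[1:3, ])), "at least 4")
  flat <- cbind(runif(6), runif(6), 0)
  expect_error(fit_affine(landmark_pairs(flat, flat)), "degenerate")
})

test_that("TPS interpolates at lambda = 0 and reduces to affine maps", {
  set.seed(4)
  s <- matrix(runif(45, 0, 10), 15, 3)
  t0 <- known_affine()
  lm <- landmark_pairs(s, apply_transform(t0, s))
  tps <- fit_tps(lm, lambda = 0)
  expect_lt(max(abs(apply_transform(tps, s) - lm$target)), 1e-9)
  # affine-consistent landmarks: warp weights vanish, map equals the affine
  expect_lt(max(abs(tps$weights)), 1e-8)
  grid <- matrix(runif(30, 0, 10), 10, 3)
  expect_lt(max(abs(apply_transform(tps, grid) - apply_transform(t0, grid))),
            1e-8)
  expect_error(landmark_pairs(s[c(1, 1, 2, 3, 4), ], s[1:5, ]), "duplicate")
  expect_error(fit_tps(landmark_pairs(s[1:4, ], s[1:4, ])), "at least 5")
})

test_that("transforms apply to every data type and compose in order", {
  fl <- flip_transform("x", 0, 10)
  pts <- matrix(runif(30, 0, 10), 10, 3)
  expect_equal(apply_transform(fl, apply_transform(fl, pts)), pts)
  t0 <- known_affine()
  seqt <- sequence_transform(fl, t0)
  expect_equal(apply_transform(seqt, pts),
               apply_transform(t0, apply_transform(fl, pts)))
  # neuron: topology untouched, cable consistent with an isotropic scale
  n <- gen_tree_neuron(40, seed = 5)
  sc <- affine_transform(cbind(diag(3) * 2, 0))
  n2 <- apply_transform(sc, n)
  expect_equal(n2$nodes$id, n$nodes$id)
  expect_equal(n2$nodes$parent_id, n$nodes$parent_id)
  expect_equal(summary_stats(n2)$cable_length,
               2 * summary_stats(n)$cable_length, tolerance = 1e-12)
  # dotprops: tangents re-derived and re-normalised
  dp <- make_dotprops(n)
  dp2 <- apply_transform(t0, dp)
  expect_equal(unname(sqrt(rowSums(dp2$vectors^2))), rep(1, nrow(dp2$points)),
               tolerance = 1e-9)
})

test_that("numeric inversion meets its round-trip contract", {
  t0 <- known_affine()
  inv <- invert_numeric(t0)
  expect_equal(inv$kind, "affine")  # closed-form short circuit
  pts <- matrix(runif(30, 0, 10), 10, 3)
  expect_lt(max(abs(apply_transform(inv, apply_transform(t0, pts)) - pts)), 1e-12)
  # identity inverts to identity
  idt <- identity_transform()
  expect_equal(invert_numeric(idt)$matrix, idt$matrix)
  # TPS on a 5x5x5 grid: round trip under 1e-6 of the bbox scale
  sc <- gen_registration_scenario("tps", seed = 6)
  tps <- fit_tps(sc$landmarks)
  g <- as.matrix(expand.grid(seq(10, 90, length.out = 5),
                             seq(10, 70, length.out = 5),
                             seq(10, 50, length.out = 5)))
  bbox <- sqrt(sum((c(100, 80, 60))^2))
  inv_tps <- invert_numeric(tps, tolerance = 1e-8 * bbox)
  back <- apply_transform(tps, apply_transform(inv_tps, g))
  expect_lt(max(abs(back - g)), 1e-6 * bbox)
})

test_that("bridging composes, inverts and prefers native directions", {
  sc <- gen_registration_scenario("affine", seed = 3, chain = TRUE)
  x <- matrix(runif(30, 10, 50), 10, 3)
  ab <- sc$registry$bridges[[1]]$transform
  bc <- sc$registry$bridges[[2]]$transform
  expect_lt(max(abs(bridge(x, "A", "C", sc$registry) -
                      apply_transform(bc, apply_transform(ab, x)))), 1e-12)
  expect_equal(bridge(x, "A", "A", sc$registry), x)
  # only reverse edge available: numeric inversion route
  rev_reg <- bridging_registry(sc$spaces["A" != names(sc$spaces) | TRUE],
                               list(list(from = "B", to = "A",
                                         transform = invert_numeric(ab))))
  ba <- bridge(x, "A", "B", rev_reg)
  expect_lt(max(abs(ba - apply_transform(ab, x))), 1e-9)
  expect_error(bridge(x, "A", "Z", sc$registry), "unknown template space")
  noedge <- bridging_registry(sc$spaces, list())
  expect_error(bridge(x, "A", "B", noedge), "no path")
  # non-invertible edges cannot be traversed backwards
  oneway <- bridging_registry(sc$spaces,
                              list(list(from = "A", to = "B", transform = ab,
                                        invertible = FALSE)))
  expect_error(bridge(x, "B", "A", oneway), "no path")
  path <- attr(bridge_transform(sc$registry, "A", "C"), "path")
  expect_equal(path, c("A", "B", "C"))
})

test_that("mirroring is an involution and respects corrections", {
  sp <- template_space("T", bbox_lo = c(0, 0, 0), bbox_hi = c(100, 80, 60))
  pts <- matrix(runif(30, 0, 60), 10, 3)
  expect_equal(mirror(mirror(pts, sp), sp), pts)
  # TPS correction fitted from symmetric landmarks: round trip stays tight
  set.seed(8)
  src <- matrix(runif(60, 10, 50), 20, 3)
  corr <- fit_tps(landmark_pairs(src, src + 0.5 * sin(src / 20)))
  sp2 <- template_space("T2", bbox_lo = c(0, 0, 0), bbox_hi = c(100, 80, 60),
                        mirror_correction = corr)
  m1 <- mirror(pts, sp2)
  expect_true(all(is.finite(m1)))
  # unit mismatch errors
  n <- gen_tree_neuron(20, seed = 2, unit = "nm")
  expect_error(mirror(n, sp), "unit mismatch")
})

test_that("segment symmetry scores separate symmetric and unilateral cable", {
  sp <- template_space("T", bbox_lo = c(0, 0, 0), bbox_hi = c(100, 80, 60))
  sym <- gen_symmetric_neuron(sp, n_half = 50, seed = 5)
  ss <- mirror_symmetry_scores(sym, sp)
  expect_true(all(ss$score > 0.99))
  # a neuron confined to one hemisphere, far from the midplane: scores ~ 0
  uni <- gen_tree_neuron(40, seed = 6, origin = c(10, 40, 30), unit = sp$unit)
  uni$nodes$x <- uni$nodes$x * 0.2 + 5  # keep well left of midplane 50
  su <- mirror_symmetry_scores(uni, sp)
  expect_true(all(su$score < 0.05))
  # single-segment neuron gives one score
  ch <- chain_neuron(8)
  ch$unit <- sp$unit
  expect_equal(nrow(mirror_symmetry_scores(ch, sp)), 1L)
})
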