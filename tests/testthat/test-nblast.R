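test_that("dotprops tangents and alpha reflect local PCA", {
  dp <- make_dotprops(cbind(0:5, 0, 0), k = 5)
  expect_true(all(abs(abs(dp$vectors[, 1]) - 1) < 1e-12))
  expect_true(all(abs(dp$alpha - 1) < 1e-12))
  # circle of radius 100: tangents align with local chords
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  circ <- cbind(100 * cos(th), 100 * sin(th), 0)
  dpc <- make_dotprops(circ, k = 5)
  chord <- cbind(-sin(th), cos(th), 0)
  agree <- abs(rowSums(dpc$vectors * chord))
  expect_true(all(agree > 1 - 1e-3))
  expect_error(make_dotprops(cbind(1:3, 0, 0), k = 5), "k = 5")
  expect_error(make_dotprops(matrix(1, 6, 3), k = 5), "degenerate")
  expect_true(all(abs(sqrt(rowSums(dpc$vectors^2)) - 1) < 1e-9))
})

test_that("pairwise scores match closed forms and normalisations", {
  line1 <- make_dotprops(cbind(0:9, 0, 0), k = 5)
  line2 <- make_dotprops(cbind(0:9, 3, 0), k = 5)
  expect_equal(nblast_pair(line1, line2, normalisation = "raw"),
               10 * exp(-0.5), tolerance = 1e-9)
  expect_equal(nblast_pair(line1, line2, normalisation = "self"),
               exp(-0.5), tolerance = 1e-9)
  expect_equal(nblast_pair(line1, line1, normalisation = "self"), 1,
               tolerance = 1e-12)
  # coincident points with orthogonal tangents score zero
  a <- make_dotprops(cbind(0:9, 0, 0), k = 5)
  b <- make_dotprops(cbind(0, 0:9, 0), k = 5)
  b$points <- a$points  # same positions, orthogonal tangents
  expect_equal(nblast_pair(a, b, normalisation = "raw"), 0, tolerance = 1e-12)
  # unit mismatch is an error
  c1 <- make_dotprops(cbind(0:9, 0, 0), k = 5, unit = "um")
  c2 <- make_dotprops(cbind(0:9, 0, 0), k = 5, unit = "nm")
  expect_error(nblast_pair(c1, c2), "unit mismatch")
})

test_that("matrix scorers bin and clamp as documented", {
  sm <- scoring_matrix(c(0, 1, 2), c(0, 0.5, 1),
                       rbind(c(1, 2), c(3, 4)))
  p <- make_dotprops(cbind(0:9, 0, 0), k = 5)
  q <- make_dotprops(cbind(0:9, 0.5, 0), k = 5)   # d = 0.5, a = 1
  expect_equal(nblast_pair(p, q, scorer = sm, normalisation = "raw"), 10 * 2)
  far <- make_dotprops(cbind(0:9, 50, 0), k = 5)  # d out of range: clamps
  expect_equal(nblast_pair(p, far, scorer = sm, normalisation = "raw"), 10 * 4)
})

test_that("all-by-all tables are symmetric with unit diagonal", {
  fam <- gen_morph_families(2, 4, n_nodes = 50, seed = 11)
  st <- nblast_all_by_all(fam)
  expect_equal(max(abs(st$scores - t(st$scores))), 0, tolerance = 1e-12)
  expect_equal(unname(diag(st$scores)), rep(1, length(fam)))
  one <- nblast_all_by_all(fam[1])
  expect_equal(dim(one$scores), c(1L, 1L))
  expect_equal(one$scores[1, 1], 1)
  # planted families separate: min within > max between
  f <- nl_metadata(fam)$family
  within <- st$scores[outer(f, f, "==") & row(st$scores) != col(st$scores)]
  between <- st$scores[outer(f, f, "!=")]
  expect_gt(min(within), max(between))
})

test_that("nearest-neighbour step equals brute force", {
  set.seed(42)
  q <- matrix(runif(1500), 500, 3)
  t <- matrix(runif(1500), 500, 3)
  nn <- RANN::nn2(t, q, k = 1)
  bf <- brute_nn1(q, t)
  expect_equal(nn$nn.idx[, 1], bf$idx)
  expect_equal(nn$nn.dists[, 1], bf$dist, tolerance = 1e-12)
})

test_that("parametric scores are rigid-motion invariant and decay with offset", {
  set.seed(7)
  pts <- matrix(runif(150, 0, 10), 50, 3)
  dp <- make_dotprops(pts, k = 5)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- affine_transform(cbind(R, c(5, -2, 1)))
  s0 <- nblast_pair(dp, dp, normalisation = "raw")
  dpr <- apply_transform(tr, dp)
  expect_equal(nblast_pair(dpr, dpr, normalisation = "raw"), s0, tolerance = 1e-9)
  offs <- c(0, 1, 2, 4, 8)
  scores <- vapply(offs, function(o) {
    shifted <- dp
    shifted$points <- dp$points + cbind(o, 0, 0)[rep(1, nrow(dp$points)), ]
    nblast_pair(dp, shifted, normalisation = "raw")
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("clustering recovers planted families and handles edge cases", {
  fam <- gen_morph_families(2, 10, n_nodes = 60, seed = 21)
  st <- nblast_all_by_all(fam)
  cl <- cluster_scores(st, k = 2)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(cl$labels, nl_metadata(fam)$family), 1)
  # k = N: all singletons
  clN <- cluster_scores(st, k = length(fam))
  expect_equal(length(unique(clN$labels)), length(fam))
  expect_error(cluster_scores(st, k = length(fam) + 1), "k must be")
  # duplicate neurons merge at height 0
  dup <- nblast_all_by_all(c(fam[1], fam[1]))
  cld <- cluster_scores(dup, k = 1)
  expect_lt(min(cld$hclust$height), 1e-12)
  # Newick export parses back with the same tips
  tree <- ape::read.tree(text = cluster_scores(st, k = 2)$newick)
  expect_setequal(tree$tip.label, names(fam))
  expect_error(cluster_scores(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
})

test_that("principal-axes alignment recovers variance ordering", {
  set.seed(3)
  base <- cbind(rnorm(200, sd = 5), rnorm(200, sd = 2), rnorm(200, sd = 0.5))
  th <- 0.9
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  rotated <- base %*% t(R) + 7
  al <- align_principal_axes(rotated)
  v_al <- apply(al, 2, var)
  expect_true(all(diff(v_al) <= 1e-12))
  # variances along the recovered axes = covariance eigenvalues of the cloud
  expect_equal(sort(v_al, decreasing = TRUE),
               eigen(stats::cov(base), symmetric = TRUE)$values,
               tolerance = 1e-9)
  expect_equal(unname(colMeans(al)), c(0, 0, 0), tolerance = 1e-9)
  # spherical cloud: identity fallback with a warning
  sph <- matrix(rnorm(30), 10, 3)
  sph <- rbind(sph, -sph)  # perfectly symmetric but anisotropic enough?
  expect_warning(align_principal_axes(diag(3)[c(1, 2, 3, 1, 2, 3), ] * 1),
                 "degenerate|fewer")
})
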