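# Deterministic generators of skeletons, synapse distributions,
# morphological families, symmetric populations and registration
# scenarios. Every generator is a pure function of its arguments (seed
# included) and leaves the caller's RNG state untouched.

#' Generate a random tree skeleton
#'
#' Grows a rooted tree by stepwise tip extension: at each step a random
#' active tip is extended by `step_length` along its (slowly wandering)
#' direction plus isotropic jitter; with probability
#' `branch_probability` the new node also spawns a second growing tip.
#'
#' @param n_nodes total node count.
#' @param branch_probability per-step probability of creating a branch.
#' @param step_length mean edge length (length units).
#' @param jitter s.d. of the isotropic positional noise per step.
#' @param origin 3-vector position of the root.
#' @param seed integer seed; identical arguments give identical neurons.
#' @param unit unit label.
#' @return a [neuron][build_neuron] (root = node 1, soma at the root).
#' @export
gen_tree_neuron <- function(n_nodes = 100L, branch_probability = 0.1,
                            step_length = 1, jitter = 0.2,
                            origin = c(0, 0, 0), seed = 1L, unit = NULL) {
  stopifnot(n_nodes >= 1L, branch_probability >= 0, branch_probability <= 1,
            step_length > 0, jitter >= 0)
  with_seed(seed, {
    pos <- matrix(NA_real_, n_nodes, 3L)
    parent <- integer(n_nodes)
    pos[1L, ] <- origin
    parent[1L] <- -1L
    # active tips: node index + current direction
    d0 <- stats::rnorm(3); d0 <- d0 / sqrt(sum(d0^2))
    tips <- list(list(node = 1L, dir = d0))
    i <- 1L
    while (i < n_nodes) {
      ti <- sample.int(length(tips), 1L)
      tip <- tips[[ti]]
      dir <- tip$dir + stats::rnorm(3, sd = 0.3)
      dir <- dir / sqrt(sum(dir^2))
      i <- i + 1L
      pos[i, ] <- pos[tip$node, ] + dir * step_length + stats::rnorm(3, sd = jitter)
      parent[i] <- tip$node
      tips[[ti]] <- list(node = i, dir = dir)
      if (stats::runif(1) < branch_probability && i < n_nodes) {
        bdir <- dir + stats::rnorm(3, sd = 1)
        bdir <- bdir / sqrt(sum(bdir^2))
        tips[[length(tips) + 1L]] <- list(node = i, dir = bdir)
      }
    }
    build_neuron(data.frame(id = seq_len(n_nodes), parent_id = parent,
                            x = pos[, 1], y = pos[, 2], z = pos[, 3]),
                 soma_id = 1L, unit = unit,
                 meta = list(generator = "gen_tree_neuron", seed = seed))
  })
}

#' Generate a polarised neuron with ground-truth compartments
#'
#' Plants the classic insect-neuron layout: a synapse-free cell-body
#' fibre from the soma to a branch node, from which a postsynapse-rich
#' dendritic subtree and a presynapse-rich axonal subtree grow. With
#' purity `p`, a fraction `p` of presynapses land on the axon (the rest
#' on the dendrite) and symmetrically for postsynapses.
#'
#' @param seed integer seed.
#' @param purity fraction of each polarity on its home compartment.
#' @param n_fiber,n_arbor node counts of the fibre and of each arbour.
#' @param n_pre,n_post synapse counts.
#' @param unit unit label.
#' @return list with `neuron` and `truth` (named character vector node id
#'   -> planted compartment). The synapse-free linking cable between the
#'   primary branch point and each arbour is planted as `"intervening"`
#'   (the maximum-flow plateau, the insect "primary dendrite"): the split
#'   may validly assign it to either adjacent compartment, so recovery
#'   metrics should score it as unconstrained.
#' @export
gen_polarised_neuron <- function(seed = 1L, purity = 0.95,
                                 n_fiber = 10L, n_arbor = 60L,
                                 n_pre = 60L, n_post = 80L, unit = NULL) {
  stopifnot(purity >= 0, purity <= 1, n_fiber >= 2L, n_arbor >= 5L)
  with_seed(seed, {
    # cell body fibre: straight-ish chain up in z
    fiber <- cbind(stats::rnorm(n_fiber, sd = 0.1),
                   stats::rnorm(n_fiber, sd = 0.1),
                   seq(0, by = 1.5, length.out = n_fiber))
    dend <- gen_tree_neuron(n_arbor, branch_probability = 0.15, seed = seed + 101L,
                            origin = c(0, 0, 0))
    axon <- gen_tree_neuron(n_arbor, branch_probability = 0.15, seed = seed + 202L,
                            origin = c(0, 0, 0))
    top <- fiber[n_fiber, ]
    # linking neurites from the fibre top to each arbour origin, sampled at
    # the skeleton's internode spacing (reconstructions do not contain long
    # bare edges); the link carries its arbour's compartment label
    link_chain <- function(from, to, step = 1.5) {
      m <- max(1L, ceiling(sqrt(sum((to - from)^2)) / step))
      s <- seq_len(m - 1L) / m
      if (length(s) == 0L) return(matrix(numeric(0), 0, 3))
      outer(rep(1, length(s)), from) + outer(s, to - from)
    }
    d_origin <- top + c(-8, 0, 3)
    a_origin <- top + c(8, 0, 3)
    d_link <- link_chain(top, d_origin)
    a_link <- link_chain(top, a_origin)
    dxyz <- sweep(neuron_xyz(dend), 2L, -d_origin)
    axyz <- sweep(neuron_xyz(axon), 2L, -a_origin)
    nd_link <- nrow(d_link); na_link <- nrow(a_link)
    n_tot <- n_fiber + nd_link + n_arbor + na_link + n_arbor
    ids <- seq_len(n_tot)
    d_link_ids <- n_fiber + seq_len(nd_link)
    dend_ids <- n_fiber + nd_link + seq_len(n_arbor)
    a_link_ids <- n_fiber + nd_link + n_arbor + seq_len(na_link)
    axon_ids <- n_fiber + nd_link + n_arbor + na_link + seq_len(n_arbor)
    chain_parents <- function(ids, attach_to) {
      if (length(ids) == 0L) integer(0) else c(attach_to, ids[-length(ids)])
    }
    d_attach <- if (nd_link) d_link_ids[nd_link] else n_fiber
    a_attach <- if (na_link) a_link_ids[na_link] else n_fiber
    parent <- c(-1L, seq_len(n_fiber - 1L),                      # fibre chain
                chain_parents(d_link_ids, n_fiber),
                ifelse(dend$nodes$parent_id == -1L, d_attach,
                       dend$nodes$parent_id + (dend_ids[1] - 1L)),
                chain_parents(a_link_ids, n_fiber),
                ifelse(axon$nodes$parent_id == -1L, a_attach,
                       axon$nodes$parent_id + (axon_ids[1] - 1L)))
    pos <- rbind(fiber, d_link, dxyz, a_link, axyz)
    truth <- c(rep("cell_body_fiber", n_fiber),
               rep("intervening", nd_link), rep("dendrite", n_arbor),
               rep("intervening", na_link), rep("axon", n_arbor))
    names(truth) <- ids

    place <- function(n_syn, home, away, polarity, id0) {
      on_home <- stats::rbinom(1L, n_syn, purity)
      at <- c(sample(home, on_home, replace = TRUE),
              sample(away, n_syn - on_home, replace = TRUE))
      data.frame(connector_id = id0 + seq_len(n_syn), node_id = at,
                 polarity = polarity,
                 x = pos[at, 1], y = pos[at, 2], z = pos[at, 3])
    }
    conn <- rbind(
      if (n_pre > 0L) place(n_pre, axon_ids, dend_ids, "presynapse", 0L),
      if (n_post > 0L) place(n_post, dend_ids, axon_ids, "postsynapse", 1000L))
    neuron <- build_neuron(
      data.frame(id = ids, parent_id = parent,
                 x = pos[, 1], y = pos[, 2], z = pos[, 3]),
      connectors = conn, soma_id = 1L, unit = unit,
      meta = list(generator = "gen_polarised_neuron", seed = seed,
                  purity = purity))
    list(neuron = neuron, truth = truth)
  })
}

#' Generate planted morphological families
#'
#' Each family is an archetype tree plus small per-neuron coordinate
#' jitter; families are translated well apart so within-family distances
#' are much smaller than between-family distances.
#'
#' @param n_families number of archetypes (>= 1).
#' @param n_per_family members per family.
#' @param jitter_sd per-node coordinate jitter (length units).
#' @param n_nodes archetype size.
#' @param seed integer seed.
#' @param unit unit label.
#' @return a [neuronlist()] whose metadata has a `family` column.
#' @export
gen_morph_families <- function(n_families = 2L, n_per_family = 10L,
                               jitter_sd = 0.25, n_nodes = 80L, seed = 1L,
                               unit = NULL) {
  stopifnot(n_families >= 1L, n_per_family >= 1L, jitter_sd >= 0)
  with_seed(seed, {
    neurons <- list()
    fam <- integer(0)
    for (f in seq_len(n_families)) {
      arch <- gen_tree_neuron(n_nodes, branch_probability = 0.12,
                              seed = seed + 1000L * f,
                              origin = c(50 * (f - 1L), 0, 0), unit = unit)
      for (m in seq_len(n_per_family)) {
        nrn <- arch
        noise <- matrix(stats::rnorm(3L * n_nodes, sd = jitter_sd), n_nodes, 3L)
        nrn$nodes$x <- nrn$nodes$x + noise[, 1]
        nrn$nodes$y <- nrn$nodes$y + noise[, 2]
        nrn$nodes$z <- nrn$nodes$z + noise[, 3]
        nrn$meta$family <- f
        key <- sprintf("f%d_n%02d", f, m)
        neurons[[key]] <- nrn
        fam <- c(fam, f)
      }
    }
    neuronlist(neurons, data.frame(key = names(neurons), family = fam))
  })
}

#' Generate a bilaterally symmetric neuron
#'
#' A half-arbour grown on one side of the midplane, mirrored exactly
#' about it, the two halves joined at a root on the plane. Useful for
#' exercising mirroring and symmetry scoring with known ground truth.
#'
#' @param space a [template_space()]; symmetry is about the midplane of
#'   the space's mirror axis.
#' @param n_half nodes per hemisphere.
#' @param seed integer seed.
#' @param asymmetry s.d. of coordinate noise added to one side only
#'   (0 = perfect symmetry).
#' @return a [neuron][build_neuron] in the space's unit.
#' @export
gen_symmetric_neuron <- function(space, n_half = 60L, seed = 1L, asymmetry = 0) {
  ai <- match(space$mirror_axis, c("x", "y", "z"))
  mid <- (space$bbox_lo[ai] + space$bbox_hi[ai]) / 2
  with_seed(seed, {
    half <- gen_tree_neuron(n_half, branch_probability = 0.12, seed = seed + 7L,
                            origin = c(0, 0, 0), unit = space$unit)
    hx <- neuron_xyz(half)
    # push the half strictly into one hemisphere (mirror-axis coordinate > 0)
    hx[, ai] <- abs(hx[, ai] - hx[1, ai]) + 0.5
    hx2 <- hx
    hx2[, ai] <- -hx2[, ai]
    if (asymmetry > 0) {
      hx2 <- hx2 + matrix(stats::rnorm(length(hx2), sd = asymmetry),
                          nrow(hx2), 3L)
    }
    root_pos <- hx[1, ]; root_pos[ai] <- 0
    pos <- rbind(root_pos, hx, hx2)
    # recentre into the template bounding box, midplane on the mirror axis
    pos[, ai] <- pos[, ai] + mid
    for (d in setdiff(1:3, ai)) {
      pos[, d] <- pos[, d] - mean(range(pos[, d])) +
        (space$bbox_lo[d] + space$bbox_hi[d]) / 2
    }
    n <- n_half
    half_parent <- function(offset) {
      ifelse(half$nodes$parent_id == -1L, 1L, half$nodes$parent_id + 1L + offset)
    }
    parent <- c(-1L, half_parent(0L), half_parent(n))
    build_neuron(data.frame(id = seq_len(2L * n + 1L), parent_id = parent,
                            x = pos[, 1], y = pos[, 2], z = pos[, 3]),
                 soma_id = 1L, unit = space$unit,
                 meta = list(generator = "gen_symmetric_neuron", seed = seed))
  })
}

#' Generate a registration scenario with known ground truth
#'
#' Two (optionally three) template spaces wired by a planted transform;
#' the emitted landmarks are exactly consistent with the ground truth, so
#' fitting them recovers the planted map.
#'
#' @param kind `"affine"`, `"tps"` or `"flip+tps"`.
#' @param seed integer seed.
#' @param n_landmarks landmark-pair count.
#' @param chain if `TRUE`, adds a third space `C` with a second affine
#'   bridge `B -> C`.
#' @return list with `spaces` (named list), `registry`
#'   ([bridging_registry()]), `landmarks` ([landmark_pairs()]),
#'   `truth` (the planted `transform`), and `neuron` (a test neuron in
#'   space A).
#' @export
gen_registration_scenario <- function(kind = c("affine", "tps", "flip+tps"),
                                      seed = 1L, n_landmarks = 27L,
                                      chain = FALSE) {
  kind <- match.arg(kind)
  with_seed(seed, {
    lo <- c(0, 0, 0); hi <- c(100, 80, 60)
    A <- template_space("A", bbox_lo = lo, bbox_hi = hi)
    B <- template_space("B", bbox_lo = lo - 20, bbox_hi = hi * 1.3 + 20)
    # small random rotation + anisotropic scale + translation
    ang <- stats::runif(3, -0.2, 0.2)
    Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
                c(0, sin(ang[1]), cos(ang[1])))
    Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
                c(-sin(ang[2]), 0, cos(ang[2])))
    Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
                c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
    S <- diag(stats::runif(3, 0.9, 1.25))
    Amat <- Rz %*% Ry %*% Rx %*% S
    bvec <- stats::runif(3, -10, 10)
    affine_truth <- affine_transform(cbind(Amat, bvec))

    # control grid spanning space A
    g1 <- seq(lo[1], hi[1], length.out = 3)
    g2 <- seq(lo[2], hi[2], length.out = 3)
    g3 <- seq(lo[3], hi[3], length.out = 3)
    grid <- as.matrix(expand.grid(g1, g2, g3))
    truth <- switch(kind,
      affine = affine_truth,
      tps = ,
      "flip+tps" = {
        # smooth warp: TPS interpolating the affine image plus a small
        # sinusoidal displacement at the control grid
        disp <- 2 * cbind(sin(grid[, 1] / 30), cos(grid[, 2] / 25),
                          sin(grid[, 3] / 20))
        warp <- fit_tps(landmark_pairs(grid, tf_points(affine_truth, grid) + disp))
        if (kind == "flip+tps") {
          sequence_transform(flip_transform("x", lo[1], hi[1]), warp)
        } else {
          warp
        }
      })
    src <- if (n_landmarks == nrow(grid)) grid else {
      jitter <- matrix(stats::runif(3L * n_landmarks, 0, 1), n_landmarks, 3L)
      sweep(jitter, 2L, hi - lo, "*") + rep(lo, each = n_landmarks)
    }
    if (kind != "affine") src <- grid  # control grid: refitting is exact
    lmk <- landmark_pairs(src, tf_points(truth, src))
    bridges <- list(list(from = "A", to = "B", transform = truth,
                         invertible = TRUE))
    spaces <- list(A = A, B = B)
    if (chain) {
      C <- template_space("C", bbox_lo = lo - 40, bbox_hi = hi * 1.5)
      t_bc <- affine_transform(cbind(diag(c(1.1, 0.95, 1.05)), c(5, -3, 2)))
      bridges[[2]] <- list(from = "B", to = "C", transform = t_bc,
                           invertible = TRUE)
      spaces$C <- C
    }
    registry <- bridging_registry(spaces, bridges)
    nrn <- gen_tree_neuron(60L, seed = seed + 11L,
                           origin = (lo + hi) / 2, unit = A$unit)
    list(spaces = spaces, registry = registry, landmarks = lmk,
         truth = truth, neuron = nrn)
  })
}
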