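# Skeleton measurement and editing. Endpoint convention: undirected
# degree-1 nodes, so an unbranched root counts as an endpoint; a branch
# point is a node with >= 2 children.

#' Summary statistics of a neuron
#'
#' @param neuron a [neuron][build_neuron].
#' @return list of class `summary_stats`: `n_nodes`, `n_branch_points`,
#'   `n_endpoints`, `cable_length` (sum of parent-edge Euclidean lengths,
#'   neuron units), `n_components`, `n_pre`, `n_post`.
#' @export
summary_stats <- function(neuron) {
  deg <- node_degrees(neuron)
  ch <- children_rows(neuron)
  structure(list(
    n_nodes = nrow(neuron$nodes),
    n_branch_points = sum(lengths(ch) >= 2L),
    n_endpoints = sum(deg <= 1L),  # deg 0 = isolated single-node component
    cable_length = sum(edge_lengths(neuron)),
    n_components = n_components(neuron),
    n_pre = sum(neuron$connectors$polarity == "presynapse"),
    n_post = sum(neuron$connectors$polarity == "postsynapse")
  ), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(paste0("nodes %d | branch points %d | endpoints %d | ",
                     "cable %.6g | components %d | pre %d | post %d\n"),
              x$n_nodes, x$n_branch_points, x$n_endpoints, x$cable_length,
              x$n_components, x$n_pre, x$n_post))
  invisible(x)
}

#' Strahler order of every node
#'
#' Standard Strahler numbering on the rooted tree: leaves are order 1; a
#' branch point whose children have orders `o1..ok` takes `max(o)` when
#' the maximum is attained by one child and `max(o) + 1` otherwise.
#' Unbranched interior nodes inherit their single child's order, so order
#' is constant along a branch.
#'
#' @param neuron a single-tree [neuron][build_neuron].
#' @return named integer vector, names = node ids.
#' @export
strahler_order <- function(neuron) {
  assert_single_tree(neuron, "strahler_order")
  ch <- children_rows(neuron)
  n <- nrow(neuron$nodes)
  ord <- integer(n)
  # process in an order where children precede parents: BFS from root, reversed
  root_row <- match(neuron_root(neuron), neuron$nodes$id)
  bfs <- integer(0)
  queue <- root_row
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    bfs <- c(bfs, v)
    queue <- c(queue, ch[[v]])
  }
  for (v in rev(bfs)) {
    kids <- ch[[v]]
    if (length(kids) == 0L) {
      ord[v] <- 1L
    } else if (length(kids) == 1L) {
      ord[v] <- ord[kids]
    } else {
      m <- max(ord[kids])
      ord[v] <- if (sum(ord[kids] == m) > 1L) m + 1L else m
    }
  }
  stats::setNames(ord, neuron$nodes$id)
}

#' Prune a neuron by Strahler order
#'
#' @param neuron a single-tree [neuron][build_neuron].
#' @param min_order keep nodes with order `>= min_order`; alternatively
#'   supply `keep`, a predicate on the order vector.
#' @param keep optional function order -> logical.
#' @return the pruned `neuron` (re-validated; dropped connectors/tags are
#'   logged).
#' @export
prune_by_strahler <- function(neuron, min_order = 2L, keep = NULL) {
  ord <- strahler_order(neuron)
  sel <- if (is.null(keep)) ord >= min_order else keep(ord)
  if (!any(sel)) stop("empty result: predicate removes all nodes")
  subset_neuron_rows(neuron, sel)
}

#' Longest path through a neuron (its spine)
#'
#' The maximum-cable-length path between two endpoints (the edge-weighted
#' tree diameter). Ties are broken towards the lexicographically smallest
#' sorted endpoint-id pair, for reproducibility.
#'
#' @param neuron a single-tree [neuron][build_neuron].
#' @return list with `path` (node ids along the spine) and `length`.
#' @export
spine <- function(neuron) {
  assert_single_tree(neuron, "spine")
  if (nrow(neuron$nodes) == 1L) {
    return(list(path = neuron$nodes$id, length = 0))
  }
  deg <- node_degrees(neuron)
  eps <- neuron$nodes$id[deg == 1L]
  g <- neuron_graph(neuron)
  dm <- igraph::distances(g, v = as.character(eps), to = as.character(eps),
                          weights = igraph::E(g)$weight)
  best <- max(dm)
  hits <- which(dm >= best - 1e-12 * max(best, 1), arr.ind = TRUE)
  pairs <- t(apply(hits, 1L, function(h) sort(c(eps[h[1]], eps[h[2]]))))
  pairs <- unique(pairs[pairs[, 1] != pairs[, 2], , drop = FALSE])
  pick <- pairs[order(pairs[, 1], pairs[, 2])[1], ]
  vp <- igraph::shortest_paths(g, as.character(pick[1]), as.character(pick[2]),
                               weights = igraph::E(g)$weight)$vpath[[1]]
  list(path = as.integer(igraph::V(g)$name[vp]), length = best)
}

#' Geodesic (within-skeleton) distances
#'
#' Path lengths measured along the skeleton between node ids.
#'
#' @param neuron a single-tree [neuron][build_neuron].
#' @param from,to node-id vectors (default: all nodes).
#' @return |from| x |to| matrix, dimnames = node ids.
#' @export
geodesic_distances <- function(neuron, from = NULL, to = NULL) {
  assert_single_tree(neuron, "geodesic_distances")
  ids <- neuron$nodes$id
  from <- from %||% ids
  to <- to %||% ids
  if (!all(c(from, to) %in% ids)) {
    stop("unknown node id: ",
         paste(setdiff(c(from, to), ids), collapse = ", "))
  }
  g <- neuron_graph(neuron)
  dm <- igraph::distances(g, v = as.character(from), to = as.character(to),
                          weights = igraph::E(g)$weight)
  dimnames(dm) <- list(as.character(from), as.character(to))
  dm
}

#' Sholl profile of a neuron
#'
#' For each radius, counts skeleton-sphere crossings: edges whose
#' endpoint distances to the center strictly straddle the radius, plus
#' nodes lying exactly on the sphere (a deterministic convention;
#' measure-zero for real data).
#'
#' @param neuron a [neuron][build_neuron].
#' @param center 3-vector; defaults to the soma (or root) position.
#' @param radii strictly ascending positive radii.
#' @return object of class `sholl_profile`: list with `radii`, `crossings`,
#'   `center`.
#' @export
sholl_analysis <- function(neuron, center = NULL, radii) {
  radii <- as.numeric(radii)
  if (length(radii) == 0L || any(radii <= 0) || any(diff(radii) <= 0)) {
    stop("radii must be strictly ascending and positive")
  }
  xyz <- neuron_xyz(neuron)
  if (is.null(center)) {
    center <- xyz[match(neuron_root(neuron), neuron$nodes$id), ]
  }
  center <- as.numeric(center)
  d <- row_norms(xyz - rep(center, each = nrow(xyz)))
  idx <- match(neuron$nodes$parent_id, neuron$nodes$id)
  ok <- which(!is.na(idx))
  d1 <- d[ok]; d2 <- d[idx[ok]]
  crossings <- vapply(radii, function(r) {
    sum((d1 - r) * (d2 - r) < 0) + sum(d == r)
  }, numeric(1))
  structure(list(radii = radii, crossings = as.integer(crossings),
                 center = center),
            class = "sholl_profile")
}

#' @export
print.sholl_profile <- function(x, ...) {
  cat(sprintf("<sholl_profile> %d radii, peak %d crossings at r = %.4g\n",
              length(x$radii), max(x$crossings),
              x$radii[which.max(x$crossings)]))
  invisible(x)
}

#' Resample a neuron at uniform arclength spacing
#'
#' Each unbranched segment is re-parameterised by arclength with node
#' spacing at most `step` (the spacing divides the segment length, so
#' branch points and endpoints are kept exactly). Radii are interpolated
#' linearly; connectors are re-attached to the nearest new node. Interior
#' vertices of a segment are dropped, so resampling a curved polyline can
#' only shorten its chord-sum cable; straight runs are preserved exactly.
#'
#' @param neuron a single-tree [neuron][build_neuron].
#' @param step maximum node spacing (> 0), neuron units.
#' @return the resampled `neuron` (new ids 1..n, depth-first).
#' @export
resample <- function(neuron, step) {
  stopifnot(step > 0)
  assert_single_tree(neuron, "resample")
  ids <- neuron$nodes$id
  xyz <- neuron_xyz(neuron)
  rad <- neuron$nodes$radius
  segs <- segment_decomposition(neuron)$segments
  root_id <- neuron_root_ids(neuron)[1]

  new_id_of <- new.env()  # old break-node id -> new id
  next_id <- 0L
  rows <- list()
  add_row <- function(parent_new, x, y, z, r, old_id = NA_integer_) {
    next_id <<- next_id + 1L
    rows[[next_id]] <<- c(next_id, parent_new, x, y, z, r)
    if (!is.na(old_id)) assign(as.character(old_id), next_id, envir = new_id_of)
    next_id
  }
  get_new <- function(old_id) get(as.character(old_id), envir = new_id_of)
  rrow <- match(root_id, ids)
  add_row(-1L, xyz[rrow, 1], xyz[rrow, 2], xyz[rrow, 3], rad[rrow], root_id)

  if (length(segs) == 0L) {
    segs <- list()
  }
  for (path in segs) {
    ri <- match(path, ids)
    p <- xyz[ri, , drop = FALSE]
    r <- rad[ri]
    seglen <- c(0, cumsum(row_norms(diff(p))))
    L <- seglen[length(seglen)]
    parent_new <- get_new(path[1])
    if (L == 0) {  # coincident points: keep only the far break node
      add_row(parent_new, p[nrow(p), 1], p[nrow(p), 2], p[nrow(p), 3],
              r[nrow(p)], path[length(path)])
      next
    }
    m <- max(1L, ceiling(L / step - 1e-12))
    svals <- seq_len(m) / m * L
    for (s in svals) {
      j <- findInterval(s, seglen, rightmost.closed = TRUE)
      j <- min(j, nrow(p) - 1L)
      f <- (s - seglen[j]) / (seglen[j + 1L] - seglen[j])
      pos <- p[j, ] + f * (p[j + 1L, ] - p[j, ])
      rr <- if (is.na(r[j]) || is.na(r[j + 1L])) NA_real_ else r[j] + f * (r[j + 1L] - r[j])
      old <- if (s == svals[length(svals)]) path[length(path)] else NA_integer_
      parent_new <- add_row(parent_new, pos[1], pos[2], pos[3], rr, old)
    }
  }
  d <- as.data.frame(do.call(rbind, rows))
  names(d) <- c("id", "parent_id", "x", "y", "z", "radius")
  d$id <- as.integer(d$id); d$parent_id <- as.integer(d$parent_id)

  conn <- neuron$connectors
  if (nrow(conn)) {
    nn <- RANN::nn2(d[, c("x", "y", "z")],
                    as.matrix(conn[, c("x", "y", "z")]), k = 1L)
    conn$node_id <- d$id[nn$nn.idx[, 1]]
  }
  tags <- lapply(neuron$tags, function(v) {
    kept <- v[v %in% ls(envir = new_id_of)]
    unique(vapply(kept, get_new, integer(1)))
  })
  dropped <- sum(lengths(neuron$tags)) - sum(lengths(tags))
  if (dropped > 0L) skt_log("info", "resample dropped ", dropped, " tag reference(s)")
  tags <- tags[lengths(tags) > 0L]
  soma <- if (!is.null(neuron$soma_id)) get_new(neuron$soma_id) else NULL
  meta <- neuron$meta; meta$n_components <- NULL
  build_neuron(d, conn, tags, soma, neuron$unit, meta)
}

#' Split a neuron into microtubular backbone and twigs at tagged nodes
#'
#' Nodes carrying `boundary_tag` mark where the neurite loses its
#' microtubular backbone: each tagged node is the last backbone node and
#' everything strictly distal to it forms one twig. Nested tags resolve
#' to the most proximal tag (logged).
#'
#' @param neuron a single-tree [neuron][build_neuron].
#' @param boundary_tag tag name; must be present in `neuron$tags` (an
#'   empty id set is allowed and yields no twigs).
#' @return list with `backbone` (a `neuron`) and `twigs` (list of
#'   `neuron`s, one per effective tagged node).
#' @export
split_backbone_twigs <- function(neuron, boundary_tag) {
  assert_single_tree(neuron, "split_backbone_twigs")
  if (!boundary_tag %in% names(neuron$tags)) {
    stop("tag not present: ", boundary_tag)
  }
  tagged <- neuron$tags[[boundary_tag]]
  if (length(tagged) == 0L) {
    return(list(backbone = neuron, twigs = list()))
  }
  ids <- neuron$nodes$id
  ch <- children_rows(neuron)
  # subtree rows below each tagged node
  subtree_rows <- function(row) {
    out <- integer(0)
    stack <- ch[[row]]
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      out <- c(out, v)
      stack <- c(stack, ch[[v]])
    }
    out
  }
  trows <- match(tagged, ids)
  # drop tags nested inside another tagged node's subtree (keep most proximal)
  nested <- logical(length(trows))
  for (i in seq_along(trows)) {
    below <- subtree_rows(trows[i])
    nested <- nested | (trows %in% below)
  }
  if (any(nested)) {
    skt_log("info", "ignoring ", sum(nested), " nested boundary tag(s)")
  }
  eff <- trows[!nested]
  twig_rows <- lapply(eff, subtree_rows)
  all_twig <- unlist(twig_rows)
  backbone <- subset_neuron_rows(neuron, setdiff(seq_along(ids), all_twig))
  twigs <- lapply(twig_rows, function(rs) subset_neuron_rows(neuron, rs))
  list(backbone = backbone, twigs = twigs)
}
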