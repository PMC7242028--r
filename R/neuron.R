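# The neuron data model: a rooted tree skeleton (SWC-style node table),
# synapse connectors and string tags. Forests are permitted at the data
# level; operations that require a single tree say so and check.

#' Construct and validate a neuron
#'
#' The central container: a node table in SWC column order plus optional
#' synapse connectors, node tags and metadata. Validation enforces unique
#' positive node ids, an acyclic parent relation (a forest), and that every
#' connector, tag and the soma reference an existing node.
#'
#' @param nodes data.frame with columns `id`, `parent_id`, `x`, `y`, `z`,
#'   and optionally `radius` (NA allowed) and `label` (SWC structure code,
#'   default 0).
#' @param connectors optional data.frame with columns `connector_id`,
#'   `node_id`, `polarity` (`"presynapse"` or `"postsynapse"`), `x`, `y`, `z`.
#' @param tags named list mapping tag strings to integer node-id vectors.
#' @param soma_id optional node id of the soma.
#' @param unit length-unit label; all coordinates are in this unit.
#' @param meta named list of free-form metadata (id, name, source file...).
#' @param on_missing_parent `"error"` (default) or `"root"`: a `parent_id`
#'   that references no node either aborts or is promoted to a root (the
#'   repair is logged and flagged in `meta$promoted_roots`).
#' @return an object of class `neuron`.
#' @examples
#' y4 <- build_neuron(data.frame(
#'   id = 1:4, parent_id = c(-1, 1, 2, 2),
#'   x = c(0, 0, 0, 1), y = c(0, 0, 1, 0), z = c(0, 1, 1, 1)))
#' summary_stats(y4)$cable_length # 3
#' @export
build_neuron <- function(nodes, connectors = NULL, tags = list(), soma_id = NULL,
                         unit = NULL, meta = list(),
                         on_missing_parent = c("error", "root")) {
  on_missing_parent <- match.arg(on_missing_parent)
  unit <- unit %||% skt_options()$unit
  if (!is.data.frame(nodes) || nrow(nodes) == 0L) stop("node table is empty")
  need <- c("id", "parent_id", "x", "y", "z")
  if (!all(need %in% names(nodes))) {
    stop("node table must have columns: ", paste(need, collapse = ", "))
  }
  id <- as.integer(nodes$id)
  parent <- as.integer(nodes$parent_id)
  if (anyNA(id) || any(id < 1L)) stop("node ids must be positive integers")
  if (anyDuplicated(id)) stop("duplicate node ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  if (anyNA(parent)) stop("parent_id must be an integer (-1 for root)")
  if (any(parent == id)) stop("node cannot be its own parent")
  xyz <- cbind(nodes$x, nodes$y, nodes$z)
  if (any(!is.finite(xyz))) stop("non-finite node coordinates")
  radius <- if ("radius" %in% names(nodes)) as.numeric(nodes$radius) else rep(NA_real_, length(id))
  if (any(!is.na(radius) & radius < 0)) stop("negative radius")
  label <- if ("label" %in% names(nodes)) as.integer(nodes$label) else rep(0L, length(id))

  dangling <- parent != -1L & !(parent %in% id)
  if (any(dangling)) {
    if (on_missing_parent == "error") {
      stop("parent_id references missing node id: ",
           paste(unique(parent[dangling]), collapse = ", "))
    }
    skt_log("warn", "promoted ", sum(dangling), " node(s) with missing parents to roots")
    meta$promoted_roots <- id[dangling]
    parent[dangling] <- -1L
  }

  d <- data.frame(id = id, parent_id = parent,
                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                  radius = radius, label = label)

  # cycle check: with at most one parent per node, a cycle exists iff some
  # undirected component contains no root
  idx <- match(d$parent_id, d$id)             # NA for roots
  comp <- .components_from_parents(idx)
  roots_per_comp <- tabulate(comp$membership[is.na(idx)], comp$n)
  if (any(roots_per_comp == 0L)) stop("cycle in parent relation")
  meta$n_components <- comp$n

  if (!is.null(connectors) && nrow(as.data.frame(connectors)) > 0L) {
    connectors <- as.data.frame(connectors)
    cneed <- c("connector_id", "node_id", "polarity", "x", "y", "z")
    if (!all(cneed %in% names(connectors))) {
      stop("connector table must have columns: ", paste(cneed, collapse = ", "))
    }
    if (!all(connectors$polarity %in% c("presynapse", "postsynapse"))) {
      stop("connector polarity must be 'presynapse' or 'postsynapse'")
    }
    if (!all(connectors$node_id %in% d$id)) {
      stop("connector references unknown node id")
    }
    connectors$node_id <- as.integer(connectors$node_id)
    connectors$connector_id <- as.integer(connectors$connector_id)
  } else {
    connectors <- data.frame(connector_id = integer(), node_id = integer(),
                             polarity = character(),
                             x = numeric(), y = numeric(), z = numeric())
  }

  if (length(tags)) {
    if (is.null(names(tags)) || any(!nzchar(names(tags)))) stop("tags must be named")
    tags <- lapply(tags, as.integer)
    bad <- !vapply(tags, function(v) all(v %in% d$id), logical(1))
    if (any(bad)) stop("tag references unknown node id: ",
                       paste(names(tags)[bad], collapse = ", "))
  }

  if (!is.null(soma_id)) {
    soma_id <- as.integer(soma_id)
    if (length(soma_id) != 1L || !(soma_id %in% d$id)) stop("soma_id not a node id")
  }

  structure(list(nodes = d, connectors = connectors, tags = tags,
                 soma_id = soma_id, unit = unit, meta = meta),
            class = "neuron")
}

# connected components from the parent-index vector (NA = root)
.components_from_parents <- function(parent_idx) {
  n <- length(parent_idx)
  # union-find
  up <- seq_len(n)
  find <- function(i) {
    while (up[i] != i) {
      up[i] <<- up[up[i]]
      i <- up[i]
    }
    i
  }
  for (i in seq_len(n)) {
    if (!is.na(parent_idx[i])) {
      ri <- find(i); rj <- find(parent_idx[i])
      if (ri != rj) up[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  membership <- match(roots, unique(roots))
  list(membership = membership, n = length(unique(roots)))
}

#' @export
print.neuron <- function(x, ...) {
  s <- summary_stats(x)
  cat(sprintf("<neuron> %d nodes, %d branch points, %d endpoints, cable %.4g %s\n",
              s$n_nodes, s$n_branch_points, s$n_endpoints, s$cable_length, x$unit))
  if (nrow(x$connectors)) {
    cat(sprintf("  connectors: %d pre, %d post\n", s$n_pre, s$n_post))
  }
  if (length(x$tags)) cat("  tags:", paste(names(x$tags), collapse = ", "), "\n")
  invisible(x)
}

#' Is an object a neuron?
#' @param x object.
#' @return logical.
#' @export
is.neuron <- function(x) inherits(x, "neuron")

# ---- basic structural accessors (internal) ----

neuron_xyz <- function(n) as_points3(n$nodes[, c("x", "y", "z")])

neuron_root_ids <- function(n) n$nodes$id[n$nodes$parent_id == -1L]

# effective root for rooted algorithms: soma if set, else smallest root id
neuron_root <- function(n) {
  if (!is.null(n$soma_id)) return(n$soma_id)
  r <- neuron_root_ids(n)
  if (length(r) > 1L) skt_log("info", "multiple roots; using smallest id ", min(r))
  min(r)
}

n_components <- function(n) n$meta$n_components %||% {
  idx <- match(n$nodes$parent_id, n$nodes$id)
  .components_from_parents(idx)$n
}

assert_single_tree <- function(n, what = "operation") {
  if (n_components(n) != 1L) {
    stop(what, " requires a single-component neuron (found ",
         n_components(n), " components)")
  }
  invisible(TRUE)
}

# children list indexed by row; returns list of integer row indices
children_rows <- function(n) {
  idx <- match(n$nodes$parent_id, n$nodes$id)
  ch <- vector("list", nrow(n$nodes))
  ok <- which(!is.na(idx))
  for (i in ok) ch[[idx[i]]] <- c(ch[[idx[i]]], i)
  ch
}

# undirected node degree, by row
node_degrees <- function(n) {
  idx <- match(n$nodes$parent_id, n$nodes$id)
  deg <- integer(nrow(n$nodes))
  ok <- which(!is.na(idx))
  for (i in ok) {
    deg[i] <- deg[i] + 1L
    deg[idx[i]] <- deg[idx[i]] + 1L
  }
  deg
}

# lengths of parent edges by row (0 for roots)
edge_lengths <- function(n) {
  idx <- match(n$nodes$parent_id, n$nodes$id)
  xyz <- neuron_xyz(n)
  len <- numeric(nrow(xyz))
  ok <- which(!is.na(idx))
  if (length(ok)) {
    len[ok] <- row_norms(xyz[ok, , drop = FALSE] - xyz[idx[ok], , drop = FALSE])
  }
  len
}

# igraph of the skeleton, vertices named by node id, edges weighted by length
neuron_graph <- function(n, directed = FALSE) {
  idx <- match(n$nodes$parent_id, n$nodes$id)
  ok <- which(!is.na(idx))
  edges <- data.frame(from = as.character(n$nodes$id[idx[ok]]),
                      to = as.character(n$nodes$id[ok]),
                      weight = edge_lengths(n)[ok])
  igraph::graph_from_data_frame(
    edges, directed = directed,
    vertices = data.frame(name = as.character(n$nodes$id)))
}

# rebuild a valid neuron from a subset of node rows (keep: logical/row index);
# children of removed nodes become roots; connectors/tags filtered.
subset_neuron_rows <- function(n, keep) {
  d <- n$nodes[keep, , drop = FALSE]
  if (nrow(d) == 0L) stop("empty result: all nodes removed")
  d$parent_id[!(d$parent_id %in% d$id)] <- -1L
  conn <- n$connectors[n$connectors$node_id %in% d$id, , drop = FALSE]
  dropped <- nrow(n$connectors) - nrow(conn)
  if (dropped > 0L) skt_log("info", "dropped ", dropped, " connector(s) on removed nodes")
  tags <- lapply(n$tags, function(v) v[v %in% d$id])
  tags <- tags[vapply(tags, length, integer(1)) > 0L]
  soma <- if (!is.null(n$soma_id) && n$soma_id %in% d$id) n$soma_id else NULL
  meta <- n$meta
  meta$n_components <- NULL
  build_neuron(d, conn, tags, soma, n$unit, meta)
}

#' Reroot a neuron at a given node
#'
#' Reverses the parent relation along the path from the old root to
#' `new_root`. The undirected edge set, node set and all geodesic
#' distances are unchanged.
#'
#' @param neuron a single-tree [neuron][build_neuron].
#' @param new_root node id of the new root.
#' @return a rerooted `neuron`.
#' @export
reroot <- function(neuron, new_root) {
  assert_single_tree(neuron, "reroot")
  new_root <- as.integer(new_root)
  if (!(new_root %in% neuron$nodes$id)) stop("unknown node id: ", new_root)
  n <- nrow(neuron$nodes)
  adj <- vector("list", n)
  idx <- match(neuron$nodes$parent_id, neuron$nodes$id)
  for (i in which(!is.na(idx))) {
    adj[[i]] <- c(adj[[i]], idx[i])
    adj[[idx[i]]] <- c(adj[[idx[i]]], i)
  }
  start <- match(new_root, neuron$nodes$id)
  parent_new <- rep(NA_integer_, n)
  visited <- logical(n)
  visited[start] <- TRUE
  queue <- start
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!visited[w]) {
        visited[w] <- TRUE
        parent_new[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  d <- neuron$nodes
  d$parent_id <- ifelse(is.na(parent_new), -1L, d$id[parent_new])
  out <- neuron
  out$nodes <- d
  out
}

#' Renumber nodes depth-first
#'
#' Node ids are preserved verbatim by every other operation; this is the
#' single explicit renumbering: depth-first from the root, children visited
#' in increasing-id order, new ids 1..n.
#'
#' @param neuron a [neuron][build_neuron].
#' @return a `neuron` with contiguous depth-first ids.
#' @export
canonicalise <- function(neuron) {
  ch <- children_rows(neuron)
  ids <- neuron$nodes$id
  order_new <- integer(0)
  roots <- which(neuron$nodes$parent_id == -1L)
  roots <- roots[order(ids[roots])]
  for (r in roots) {
    stack <- r
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      order_new <- c(order_new, v)
      kids <- ch[[v]]
      if (length(kids)) stack <- c(stack, rev(kids[order(ids[kids])]))
    }
  }
  remap <- integer(nrow(neuron$nodes))
  remap[order_new] <- seq_along(order_new)
  d <- neuron$nodes[order_new, , drop = FALSE]
  old_ids <- neuron$nodes$id
  d$id <- seq_len(nrow(d))
  d$parent_id <- ifelse(d$parent_id == -1L, -1L,
                        remap[match(d$parent_id, old_ids)])
  rownames(d) <- NULL
  conn <- neuron$connectors
  if (nrow(conn)) conn$node_id <- remap[match(conn$node_id, old_ids)]
  tags <- lapply(neuron$tags, function(v) sort(remap[match(v, old_ids)]))
  soma <- if (!is.null(neuron$soma_id)) remap[match(neuron$soma_id, old_ids)] else NULL
  build_neuron(d, conn, tags, soma, neuron$unit, neuron$meta)
}

#' Decompose a skeleton into unbranched segments
#'
#' A segment is a maximal unbranched run of nodes between break points
#' (root, branch points and endpoints). Every edge belongs to exactly one
#' segment; consecutive ids in a segment are parent/child pairs.
#'
#' @param neuron a single-tree [neuron][build_neuron].
#' @return an object of class `segment_decomposition`: list with `segments`
#'   (list of node-id paths, each ordered away from the root) and
#'   `parent_segment` (integer index of the upstream segment, NA for
#'   segments starting at the root).
#' @export
segment_decomposition <- function(neuron) {
  assert_single_tree(neuron, "segment_decomposition")
  ids <- neuron$nodes$id
  ch <- children_rows(neuron)
  nkids <- lengths(ch)
  root_row <- match(neuron_root_ids(neuron), ids)[1]
  # break rows: root, branch points (>=2 children), leaves handled by walk end
  segments <- list()
  seg_start_row <- integer(0)  # first row of each segment (a break node)
  starts <- root_row
  while (length(starts)) {
    s <- starts[[1]]; starts <- starts[-1]
    for (k in ch[[s]]) {
      path <- c(s, k)
      v <- k
      while (nkids[v] == 1L) {
        v <- ch[[v]][1]
        path <- c(path, v)
      }
      segments[[length(segments) + 1L]] <- ids[path]
      seg_start_row <- c(seg_start_row, s)
      if (nkids[v] >= 2L) starts <- c(starts, v)
    }
  }
  seg_end_row <- vapply(segments, function(p) match(p[length(p)], ids), integer(1))
  parent_segment <- rep(NA_integer_, length(segments))
  for (i in seq_along(segments)) {
    if (seg_start_row[i] != root_row) {
      parent_segment[i] <- which(seg_end_row == seg_start_row[i])[1]
    }
  }
  structure(list(segments = segments, parent_segment = parent_segment),
            class = "segment_decomposition")
}

#' @export
print.segment_decomposition <- function(x, ...) {
  cat(sprintf("<segment_decomposition> %d segments\n", length(x$segments)))
  invisible(x)
}
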