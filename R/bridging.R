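# Template spaces, the bridging graph, mirroring and segment-wise
# symmetry scores.

#' Define a template space
#'
#' A named reference coordinate system with a unit and an axis-aligned
#' bounding box. An optional mirror-correction transform captures the
#' residual non-rigid displacement left after the plain axis flip (real
#' brains are not perfectly symmetric).
#'
#' @param name space name.
#' @param unit length-unit label.
#' @param bbox_lo,bbox_hi 3-vectors, `lo < hi` per axis.
#' @param mirror_correction optional `transform` applied after the flip by
#'   [mirror()].
#' @param mirror_axis default medio-lateral axis, `"x"`.
#' @param ... free metadata (sex, species...).
#' @return object of class `template_space`.
#' @export
template_space <- function(name, unit = NULL, bbox_lo, bbox_hi,
                           mirror_correction = NULL, mirror_axis = "x", ...) {
  bbox_lo <- as.numeric(bbox_lo); bbox_hi <- as.numeric(bbox_hi)
  stopifnot(length(bbox_lo) == 3L, length(bbox_hi) == 3L)
  if (!all(bbox_lo < bbox_hi)) stop("bounding box must have lo < hi per axis")
  unit <- unit %||% skt_options()$unit
  if (!nzchar(unit)) stop("unit label must be non-empty")
  structure(list(name = name, unit = unit, bbox_lo = bbox_lo, bbox_hi = bbox_hi,
                 mirror_correction = mirror_correction,
                 mirror_axis = mirror_axis, meta = list(...)),
            class = "template_space")
}

#' Build a bridging registry
#'
#' A directed graph of named template spaces connected by transforms.
#'
#' @param spaces list of [template_space()] objects.
#' @param bridges list of bridges, each `list(from=, to=, transform=,
#'   invertible=)`; `invertible` (default `TRUE`) marks edges that may be
#'   traversed backwards via [invert_numeric()].
#' @return object of class `bridging_registry`.
#' @export
bridging_registry <- function(spaces = list(), bridges = list()) {
  stopifnot(all(vapply(spaces, inherits, logical(1), "template_space")))
  names(spaces) <- vapply(spaces, `[[`, character(1), "name")
  for (b in bridges) {
    if (!all(c("from", "to", "transform") %in% names(b))) {
      stop("bridge needs from, to, transform")
    }
    if (!all(c(b$from, b$to) %in% names(spaces))) {
      stop("bridge endpoint not a registered space: ", b$from, " -> ", b$to)
    }
    if (identical(b$from, b$to)) stop("self-bridges are not allowed")
    stopifnot(inherits(b$transform, "transform"))
  }
  bridges <- lapply(bridges, function(b) {
    b$invertible <- isTRUE(b$invertible %||% TRUE)
    b
  })
  structure(list(spaces = spaces, bridges = bridges), class = "bridging_registry")
}

#' @export
print.bridging_registry <- function(x, ...) {
  cat(sprintf("<bridging_registry> %d spaces, %d bridges\n",
              length(x$spaces), length(x$bridges)))
  invisible(x)
}

#' Find the bridging transform between two template spaces
#'
#' Shortest path in the bridge graph (edge weight 1 forwards, 1.1 when an
#' invertible edge is traversed backwards via numeric inversion, so
#' natively constructed bridges are preferred). The path is logged.
#'
#' @param registry a [bridging_registry()].
#' @param from,to space names.
#' @param tolerance passed to [invert_numeric()] for backward edges.
#' @return a `transform` (identity when `from == to`); `attr(, "path")`
#'   records the space sequence used.
#' @export
bridge_transform <- function(registry, from, to, tolerance = 1e-6) {
  if (!all(c(from, to) %in% names(registry$spaces))) {
    stop("unknown template space: ",
         paste(setdiff(c(from, to), names(registry$spaces)), collapse = ", "))
  }
  if (identical(from, to)) {
    t <- identity_transform()
    attr(t, "path") <- from
    return(t)
  }
  edges <- list()
  for (b in registry$bridges) {
    edges[[length(edges) + 1L]] <- list(from = b$from, to = b$to, w = 1,
                                        transform = b$transform)
    if (b$invertible) {
      edges[[length(edges) + 1L]] <-
        list(from = b$to, to = b$from, w = 1.1,
             transform = invert_numeric(b$transform, tolerance = tolerance))
    }
  }
  if (length(edges) == 0L) stop("no path from '", from, "' to '", to, "'")
  el <- data.frame(from = vapply(edges, `[[`, character(1), "from"),
                   to = vapply(edges, `[[`, character(1), "to"),
                   weight = vapply(edges, `[[`, numeric(1), "w"))
  g <- igraph::graph_from_data_frame(
    el, directed = TRUE,
    vertices = data.frame(name = names(registry$spaces)))
  sp <- suppressWarnings(  # igraph warns separately about unreachable vertices
    igraph::shortest_paths(g, from, to, mode = "out",
                           weights = igraph::E(g)$weight, output = "vpath"))
  vp <- sp$vpath[[1]]
  if (length(vp) == 0L) stop("no path from '", from, "' to '", to, "'")
  path <- igraph::V(g)$name[vp]
  ts <- list()
  for (i in seq_len(length(path) - 1L)) {
    cand <- Filter(function(e) e$from == path[i] && e$to == path[i + 1L], edges)
    cand <- cand[[which.min(vapply(cand, `[[`, numeric(1), "w"))]]
    ts[[i]] <- cand$transform
  }
  skt_log("info", "bridging path: ", paste(path, collapse = " -> "))
  t <- if (length(ts) == 1L) ts[[1]] else sequence_transform(ts)
  attr(t, "path") <- path
  t
}

#' Transform data between template spaces
#'
#' Looks up (or composes) the bridging transform in the registry and
#' applies it.
#'
#' @param data points, [neuron][build_neuron], dotprops or [trimesh()].
#' @param from,to space names.
#' @param registry a [bridging_registry()].
#' @param tolerance passed to [invert_numeric()] for backward edges.
#' @return `data` mapped into space `to`.
#' @export
bridge <- function(data, from, to, registry, tolerance = 1e-6) {
  t <- bridge_transform(registry, from, to, tolerance = tolerance)
  apply_transform(t, data)
}

#' Mirror data across a template space's midplane
#'
#' Flips the medio-lateral coordinate within the space's bounding box
#' (`v -> lo + hi - v`), then applies the space's non-rigid
#' mirror-correction transform if one is registered.
#'
#' @param data points, [neuron][build_neuron], dotprops or [trimesh()].
#' @param space a [template_space()].
#' @param axis override of the space's mirror axis.
#' @return mirrored `data`.
#' @export
mirror <- function(data, space, axis = NULL) {
  stopifnot(inherits(space, "template_space"))
  axis <- axis %||% space$mirror_axis
  ai <- match(axis, c("x", "y", "z"))
  if (is.na(ai)) stop("axis must be x, y or z")
  du <- if (is.neuron(data) || inherits(data, "trimesh") ||
            inherits(data, "dotprops")) data$unit else NULL
  if (!is.null(du)) check_same_unit(du, space$unit)
  t <- flip_transform(axis, space$bbox_lo[ai], space$bbox_hi[ai])
  if (!is.null(space$mirror_correction)) {
    t <- sequence_transform(t, space$mirror_correction)
  }
  apply_transform(t, data)
}

#' Segment-wise bilateral symmetry scores
#'
#' Mirrors the neuron, then scores every unbranched segment against the
#' whole mirrored neuron with a self-normalised NBLAST: symmetric cable
#' scores near 1, unilateral cable near 0.
#'
#' @param neuron a single-tree [neuron][build_neuron] registered to
#'   `space`.
#' @param space a [template_space()].
#' @param scorer NBLAST scorer (default parametric, sigma = 3).
#' @param k dotprops neighbourhood size; segments with fewer points are
#'   scored with a reduced k (logged).
#' @return data.frame with one row per segment: `segment`, `n_nodes`,
#'   `score`.
#' @export
mirror_symmetry_scores <- function(neuron, space, scorer = NULL, k = 5L) {
  assert_single_tree(neuron, "mirror_symmetry_scores")
  scorer <- scorer %||% nblast_scorer_parametric(sigma = 3)
  mirrored <- mirror(neuron, space)
  kk <- min(k, nrow(neuron$nodes))
  if (kk < k) skt_log("info", "small neuron: dotprops built with reduced k = ", kk)
  target <- make_dotprops(mirrored, k = kk)
  # tangents come from the whole-neuron vector cloud, then each segment is
  # scored as a subset: local geometry at branch points stays comparable
  # between a segment and its mirror image
  whole <- make_dotprops(neuron, k = kk)
  segs <- segment_decomposition(neuron)$segments
  ids <- neuron$nodes$id
  scores <- vapply(seq_along(segs), function(i) {
    rows <- match(segs[[i]], ids)
    dp <- structure(list(points = whole$points[rows, , drop = FALSE],
                         vectors = whole$vectors[rows, , drop = FALSE],
                         alpha = whole$alpha[rows], k = whole$k,
                         unit = whole$unit),
                    class = "dotprops")
    nblast_pair(dp, target, scorer = scorer, normalisation = "self")
  }, numeric(1))
  data.frame(segment = seq_along(segs),
             n_nodes = lengths(segs),
             score = scores)
}
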