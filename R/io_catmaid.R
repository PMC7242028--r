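# Offline CATMAID-style compact-skeleton JSON: a 3-element array
# [[node rows], [connector rows], {tag: [node ids]}] with
# node row  = [id, parent, user, x, y, z, radius, confidence]
# conn row  = [node_id, connector_id, relation, x, y, z], relation 0 =
# presynapse, 1 = postsynapse. Exactly this dialect; no network access.

#' Read a CATMAID-style compact-skeleton JSON document
#'
#' @param file path, connection or JSON string.
#' @param unit_scale factor applied to every coordinate (and radius), e.g.
#'   `1e-3` for nanometre data destined for a micrometre template space.
#' @param unit unit label of the *output* (after scaling); default from
#'   [skt_options()].
#' @return a [neuron][build_neuron] with connectors and tags populated;
#'   `meta$unit_scale` records the factor applied. A node tagged `"soma"`
#'   becomes the `soma_id`.
#' @export
read_catmaid_skeleton_json <- function(file, unit_scale = 1, unit = NULL) {
  doc <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  if (!is.list(doc) || length(doc) < 2L) {
    stop("unsupported skeleton JSON dialect: expected [nodes, connectors, tags]")
  }
  node_rows <- doc[[1]]
  conn_rows <- if (length(doc) >= 2L) doc[[2]] else list()
  tag_map <- if (length(doc) >= 3L) doc[[3]] else list()
  if (length(node_rows) == 0L) stop("no nodes in skeleton document")
  if (any(lengths(node_rows) != 8L)) stop("malformed node row (expected 8 fields)")
  nm <- do.call(rbind, lapply(node_rows, function(r) {
    r[[2]] <- r[[2]] %||% -1  # null parent = root
    as.numeric(r[c(1, 2, 4, 5, 6, 7)])
  }))
  nodes <- data.frame(id = as.integer(nm[, 1]),
                      parent_id = as.integer(nm[, 2]),
                      x = nm[, 3] * unit_scale, y = nm[, 4] * unit_scale,
                      z = nm[, 5] * unit_scale,
                      radius = ifelse(nm[, 6] < 0, NA_real_, nm[, 6] * unit_scale),
                      label = 0L)
  conn <- NULL
  if (length(conn_rows)) {
    if (any(lengths(conn_rows) != 6L)) stop("malformed connector row (expected 6 fields)")
    cm <- do.call(rbind, lapply(conn_rows, function(r) as.numeric(r)))
    rel <- as.integer(cm[, 3])
    if (!all(rel %in% c(0L, 1L))) {
      stop("unknown relation code: ", paste(setdiff(rel, 0:1), collapse = ", "))
    }
    conn <- data.frame(connector_id = as.integer(cm[, 2]),
                       node_id = as.integer(cm[, 1]),
                       polarity = ifelse(rel == 0L, "presynapse", "postsynapse"),
                       x = cm[, 4] * unit_scale, y = cm[, 5] * unit_scale,
                       z = cm[, 6] * unit_scale)
  }
  tags <- lapply(tag_map, function(v) as.integer(unlist(v)))
  soma <- NULL
  if ("soma" %in% names(tags) && length(tags[["soma"]]) == 1L) soma <- tags[["soma"]]
  build_neuron(nodes, conn, tags, soma, unit = unit,
               meta = list(unit_scale = unit_scale))
}

#' Write a neuron as compact-skeleton JSON
#'
#' Inverse of [read_catmaid_skeleton_json()] (with `unit_scale = 1`).
#'
#' @param neuron a [neuron][build_neuron].
#' @param file path; if `NULL` the JSON string is returned.
#' @return invisibly, the JSON string.
#' @export
write_catmaid_skeleton_json <- function(neuron, file = NULL) {
  d <- neuron$nodes
  node_rows <- lapply(seq_len(nrow(d)), function(i) {
    list(d$id[i], if (d$parent_id[i] == -1L) NULL else d$parent_id[i], 1L,
         d$x[i], d$y[i], d$z[i],
         if (is.na(d$radius[i])) -1 else d$radius[i], 5L)
  })
  cn <- neuron$connectors
  conn_rows <- lapply(seq_len(nrow(cn)), function(i) {
    list(cn$node_id[i], cn$connector_id[i],
         if (cn$polarity[i] == "presynapse") 0L else 1L,
         cn$x[i], cn$y[i], cn$z[i])
  })
  tags <- lapply(neuron$tags, as.list)
  if (length(tags) == 0L) tags <- structure(list(), names = character(0)) # {}
  txt <- jsonlite::toJSON(list(node_rows, conn_rows, tags),
                          auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}
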