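# Synapse-flow centrality and axon/dendrite/cell-body-fibre splitting.
#
# With the tree rooted (soma if known), every node v separates the
# synapses into those attached within v's subtree (v inclusive) and the
# remainder. Drawing a path between each input (postsynapse) and each
# output (presynapse), the number of such paths forced through v is
#   centrifugal(v) = inputs_proximal(v)  * outputs_distal(v)
#   centripetal(v) = inputs_distal(v)    * outputs_proximal(v)
# and total flow is their sum. The neuron is split at the point of
# maximum flow.

#' Synapse-flow centrality of every node
#'
#' @param neuron a single-tree [neuron][build_neuron]; rooted at the soma
#'   if `soma_id` is set, else at the smallest root id.
#' @return object of class `flow_result`: data.frame `flows` (node_id,
#'   centrifugal, centripetal, total, n_pre_distal, n_post_distal) plus
#'   `max_flow` and `root_id`. Flows are all zero when either synapse
#'   polarity is absent.
#' @export
flow_centrality <- function(neuron) {
  assert_single_tree(neuron, "flow_centrality")
  ids <- neuron$nodes$id
  ch <- children_rows(neuron)
  root_row <- match(neuron_root(neuron), ids)
  pre_at <- tabulate(match(neuron$connectors$node_id[
    neuron$connectors$polarity == "presynapse"], ids), length(ids))
  post_at <- tabulate(match(neuron$connectors$node_id[
    neuron$connectors$polarity == "postsynapse"], ids), length(ids))
  # children-before-parents order
  bfs <- integer(0)
  queue <- root_row
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    bfs <- c(bfs, v)
    queue <- c(queue, ch[[v]])
  }
  pre_d <- pre_at; post_d <- post_at
  for (v in rev(bfs)) {
    for (k in ch[[v]]) {
      pre_d[v] <- pre_d[v] + pre_d[k]
      post_d[v] <- post_d[v] + post_d[k]
    }
  }
  n_pre <- sum(pre_at); n_post <- sum(post_at)
  centrifugal <- (n_post - post_d) * pre_d
  centripetal <- post_d * (n_pre - pre_d)
  total <- centrifugal + centripetal
  flows <- data.frame(node_id = ids, centrifugal = centrifugal,
                      centripetal = centripetal, total = total,
                      n_pre_distal = pre_d, n_post_distal = post_d)
  structure(list(flows = flows, max_flow = max(total),
                 root_id = ids[root_row], neuron = neuron),
            class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("<flow_result> max flow %d at node(s) %s\n", x$max_flow,
              paste(x$flows$node_id[x$flows$total == x$max_flow &
                                      x$max_flow > 0], collapse = ",")))
  if (!is.null(x$labels)) {
    cat("  compartments:",
        paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Split a neuron into axon, dendrite and cell-body fibre
#'
#' Splits at the maximum-flow node geodesically closest to the root (ties
#' to the smallest id). The split node's subtree and the remainder form
#' the two arbour compartments; the one with the higher presynapse
#' fraction is the axon (tie: higher absolute presynapse count). The
#' maximal connected run of zero-flow, synapse-free nodes containing the
#' root is relabelled as the cell-body fibre. All nodes attaining the
#' maximum flow are additionally reported as the flow plateau (the
#' intervening "primary dendrite" cable).
#'
#' @param neuron a single-tree [neuron][build_neuron] with at least one
#'   presynapse and one postsynapse.
#' @return a `flow_result` additionally carrying `labels` (named character
#'   vector node id -> `"axon"`/`"dendrite"`/`"cell_body_fiber"`),
#'   `split_node` and `plateau` (node ids attaining the maximum flow).
#' @export
split_axon_dendrite <- function(neuron) {
  fr <- flow_centrality(neuron)
  conn <- neuron$connectors
  if (!any(conn$polarity == "presynapse") || !any(conn$polarity == "postsynapse")) {
    stop("cannot split: need at least one synapse of each polarity")
  }
  flows <- fr$flows
  ids <- flows$node_id
  cand <- ids[flows$total == fr$max_flow]
  # geodesically closest to root, then smallest id
  gd <- geodesic_distances(neuron, from = fr$root_id, to = cand)[1, ]
  cand <- cand[gd == min(gd)]
  split_node <- min(cand)

  ch <- children_rows(neuron)
  srow <- match(split_node, ids)
  sub <- srow
  stack <- ch[[srow]]
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    sub <- c(sub, v)
    stack <- c(stack, ch[[v]])
  }
  in_D <- seq_along(ids) %in% sub
  count_syn <- function(rows, pol) {
    sum(conn$polarity == pol & conn$node_id %in% ids[rows])
  }
  pre_D <- count_syn(which(in_D), "presynapse")
  post_D <- count_syn(which(in_D), "postsynapse")
  pre_P <- count_syn(which(!in_D), "presynapse")
  post_P <- count_syn(which(!in_D), "postsynapse")
  frac_D <- if (pre_D + post_D > 0) pre_D / (pre_D + post_D) else NA_real_
  frac_P <- if (pre_P + post_P > 0) pre_P / (pre_P + post_P) else NA_real_
  axon_is_D <- if (!is.na(frac_D) && !is.na(frac_P) && frac_D != frac_P) {
    frac_D > frac_P
  } else if (pre_D != pre_P) {
    pre_D > pre_P
  } else if (is.na(frac_D) || is.na(frac_P) || frac_D == frac_P) {
    stop("unpolarised: compartments tie on presynapse fraction and count")
  }
  labels <- ifelse(in_D == axon_is_D, "axon", "dendrite")

  # cell body fibre: maximal connected zero-flow, synapse-free run holding root
  syn_rows <- match(unique(conn$node_id), ids)
  eligible <- flows$total == 0 & !(seq_along(ids) %in% syn_rows)
  root_row <- match(fr$root_id, ids)
  if (eligible[root_row]) {
    idx <- match(neuron$nodes$parent_id, ids)
    adj <- vector("list", length(ids))
    for (i in which(!is.na(idx))) {
      adj[[i]] <- c(adj[[i]], idx[i])
      adj[[idx[i]]] <- c(adj[[idx[i]]], i)
    }
    seen <- logical(length(ids))
    seen[root_row] <- TRUE
    queue <- root_row
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!seen[w] && eligible[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    labels[seen] <- "cell_body_fiber"
  }
  fr$labels <- stats::setNames(labels, ids)
  fr$split_node <- split_node
  fr$plateau <- ids[flows$total == fr$max_flow]
  fr
}
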