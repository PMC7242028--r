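# Keyed collections of neurons with one metadata record per member.

#' Build a neuronlist
#'
#' An ordered, keyed collection of neurons carrying a metadata table with
#' exactly one row per member (row order aligned with the members).
#'
#' @param neurons named list of [neuron][build_neuron] objects (names are
#'   the keys; unnamed lists get keys `"1"`, `"2"`, ...).
#' @param metadata optional data.frame, one row per neuron. A `key` column
#'   is added/checked against the list names.
#' @return an object of class `neuronlist`.
#' @export
neuronlist <- function(neurons, metadata = NULL) {
  stopifnot(is.list(neurons))
  if (!all(vapply(neurons, is.neuron, logical(1)))) {
    stop("all members must be neuron objects")
  }
  if (is.null(names(neurons))) names(neurons) <- as.character(seq_along(neurons))
  if (anyDuplicated(names(neurons))) stop("duplicate keys")
  if (is.null(metadata)) {
    metadata <- data.frame(key = names(neurons), stringsAsFactors = FALSE)
  } else {
    metadata <- as.data.frame(metadata)
    if (nrow(metadata) != length(neurons)) {
      stop("metadata must have exactly one row per neuron")
    }
    if (!"key" %in% names(metadata)) metadata$key <- names(neurons)
    if (!identical(as.character(metadata$key), names(neurons))) {
      stop("metadata keys do not match neuron keys")
    }
  }
  rownames(metadata) <- NULL
  structure(neurons, metadata = metadata, class = c("neuronlist", "list"))
}

#' Metadata table of a neuronlist
#' @param nl a [neuronlist()].
#' @return data.frame with one row per member.
#' @export
nl_metadata <- function(nl) attr(nl, "metadata")

#' @export
print.neuronlist <- function(x, ...) {
  cat(sprintf("<neuronlist> %d neurons; metadata columns: %s\n", length(x),
              paste(names(nl_metadata(x)), collapse = ", ")))
  invisible(x)
}

#' @export
`[.neuronlist` <- function(x, i, ...) {
  md <- nl_metadata(x)
  y <- unclass(x)[i]
  if (anyNA(names(y))) stop("unknown key(s) in neuronlist subset")
  keep <- match(names(y), md$key)
  neuronlist(y, md[keep, , drop = FALSE])
}

#' Filter a neuronlist by a metadata predicate
#'
#' Keeps exactly the members whose metadata row satisfies the predicate;
#' metadata rows stay aligned and order is preserved.
#'
#' @param nl a [neuronlist()].
#' @param predicate either a function taking the metadata data.frame (or a
#'   single row) and returning a logical vector/scalar, or an unevaluated
#'   expression over metadata columns (e.g. `cable_length > 500`).
#' @param env environment for expression evaluation (defaults to caller).
#' @return the filtered `neuronlist` (possibly empty).
#' @examples
#' \dontrun{subset_list(nl, cable_length > 500)}
#' @export
subset_list <- function(nl, predicate, env = parent.frame()) {
  md <- nl_metadata(nl)
  e <- substitute(predicate)
  val <- tryCatch(eval(e, md, enclos = env), error = function(err) {
    stop("predicate failed (missing metadata column?): ",
         conditionMessage(err), call. = FALSE)
  })
  if (is.function(val)) {
    keep <- vapply(seq_len(nrow(md)), function(i) {
      isTRUE(val(md[i, , drop = FALSE]))
    }, logical(1))
  } else {
    keep <- val
    if (!is.logical(keep)) stop("predicate must evaluate to a logical vector")
    if (length(keep) == 1L) keep <- rep(keep, nrow(md))
    if (length(keep) != nrow(md)) stop("predicate length does not match metadata rows")
    if (anyNA(keep)) stop("predicate evaluated to NA (missing metadata column?)")
  }
  idx <- which(keep)
  neuronlist(unclass(nl)[idx], md[idx, , drop = FALSE])
}

#' Apply a function to every neuron in a list
#'
#' Mirrors the collection-map idiom: a neuron-to-neuron function yields a
#' new `neuronlist` with the metadata carried through; any other return
#' type yields a simplified named vector (or plain list).
#'
#' @param nl a [neuronlist()].
#' @param op function of a neuron (extra arguments passed via `...`).
#' @param ... passed to `op`.
#' @param strict if `TRUE` (default) an error on member `k` aborts with a
#'   message naming `k`; if `FALSE` failures record `NA`/`NULL` and are
#'   logged.
#' @return `neuronlist` or named vector/list of results.
#' @export
apply_to_all <- function(nl, op, ..., strict = NULL) {
  strict <- strict %||% skt_options()$strict
  res <- vector("list", length(nl))
  names(res) <- names(nl)
  failed <- character(0)
  for (k in names(nl)) {
    r <- tryCatch(op(nl[[k]], ...), error = function(e) {
      if (strict) stop("apply_to_all failed on member '", k, "': ",
                       conditionMessage(e), call. = FALSE)
      skt_log("warn", "member '", k, "' failed: ", conditionMessage(e))
      failed <<- c(failed, k)
      NULL
    })
    res[[k]] <- r
  }
  ok <- setdiff(names(nl), failed)
  if (length(ok) && all(vapply(res[ok], is.neuron, logical(1)))) {
    if (length(failed)) {
      md <- nl_metadata(nl)
      return(neuronlist(res[ok], md[match(ok, md$key), , drop = FALSE]))
    }
    return(neuronlist(res, nl_metadata(nl)))
  }
  for (k in failed) res[[k]] <- NA
  if (all(vapply(res, function(r) is.atomic(r) && length(r) == 1L, logical(1)))) {
    return(unlist(res))
  }
  res
}

#' Per-neuron summary table for a neuronlist
#'
#' One row per member: node/branch/endpoint counts, cable length,
#' component count and synapse counts, prefixed by the key.
#'
#' @param nl a [neuronlist()].
#' @return data.frame.
#' @export
summary_table <- function(nl) {
  rows <- lapply(names(nl), function(k) {
    s <- summary_stats(nl[[k]])
    cbind(data.frame(key = k, stringsAsFactors = FALSE),
          as.data.frame(unclass(s)))
  })
  do.call(rbind, rows)
}
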