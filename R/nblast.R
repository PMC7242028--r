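# NBLAST morphological similarity: for each query point, find the nearest
# target point and score the (distance, |tangent dot|) pair; the raw
# score is the sum over query points. Scorers are either parametric,
#   f(d, a) = a * exp(-d^2 / (2 sigma^2)),
# or an empirical log-score lookup table (scoring_matrix).

#' Parametric NBLAST scorer
#'
#' @param sigma distance scale in query units (default 3).
#' @return a scorer object.
#' @export
nblast_scorer_parametric <- function(sigma = 3) {
  stopifnot(sigma > 0)
  structure(list(sigma = sigma), class = c("nblast_scorer_parametric", "nblast_scorer"))
}

.score_pairs <- function(scorer, d, a) {
  if (inherits(scorer, "nblast_scorer_parametric")) {
    return(a * exp(-d^2 / (2 * scorer$sigma^2)))
  }
  if (inherits(scorer, "scoring_matrix")) {
    nb_d <- length(scorer$distance_breaks) - 1L
    nb_a <- length(scorer$dot_breaks) - 1L
    bi <- pmin(pmax(findInterval(d, scorer$distance_breaks), 1L), nb_d)
    bj <- pmin(pmax(findInterval(a, scorer$dot_breaks), 1L), nb_a)
    return(scorer$scores[cbind(bi, bj)])
  }
  stop("scorer must be nblast_scorer_parametric() or a scoring_matrix")
}

#' NBLAST score of a query against a target
#'
#' @param query,target [make_dotprops()] objects in the same unit.
#' @param scorer [nblast_scorer_parametric()] (default, sigma = 3) or a
#'   [scoring_matrix()]; matrix lookups clamp out-of-range distance/dot
#'   values to the edge bins.
#' @param normalisation `"raw"` (sum over query points), `"self"` (raw
#'   divided by the query's self-score, so identical clouds score 1) or
#'   `"mean"` (mean of the two self-normalised directions, symmetric).
#' @param alpha_weighted multiply each point's contribution by the query
#'   alpha (off by default).
#' @return a single numeric score.
#' @export
nblast_pair <- function(query, target, scorer = NULL,
                        normalisation = c("raw", "self", "mean"),
                        alpha_weighted = FALSE) {
  normalisation <- match.arg(normalisation)
  scorer <- scorer %||% nblast_scorer_parametric()
  stopifnot(inherits(query, "dotprops"), inherits(target, "dotprops"))
  check_same_unit(query$unit, target$unit)
  raw_dir <- function(q, t) {
    nn <- RANN::nn2(t$points, q$points, k = 1L)
    d <- nn$nn.dists[, 1]
    a <- abs(rowSums(q$vectors * t$vectors[nn$nn.idx[, 1], , drop = FALSE]))
    a <- pmin(a, 1)
    f <- .score_pairs(scorer, d, a)
    if (alpha_weighted) f <- f * q$alpha
    sum(f)
  }
  self_norm <- function(q, t) raw_dir(q, t) / raw_dir(q, q)
  switch(normalisation,
         raw = raw_dir(query, target),
         self = self_norm(query, target),
         mean = (self_norm(query, target) + self_norm(target, query)) / 2)
}

#' All-by-all NBLAST score table
#'
#' @param x a [neuronlist()], list of dotprops, or list of neurons.
#' @param scorer see [nblast_pair()].
#' @param normalisation `"mean"` (default; symmetric grid with unit
#'   diagonal), `"self"` or `"raw"`.
#' @param k,step dotprops parameters used when members are neurons.
#' @param alpha_weighted see [nblast_pair()].
#' @return object of class `score_table`: list with `scores` (named
#'   matrix) and `normalisation`.
#' @export
nblast_all_by_all <- function(x, scorer = NULL,
                              normalisation = c("mean", "self", "raw"),
                              k = 5L, step = NULL, alpha_weighted = FALSE) {
  normalisation <- match.arg(normalisation)
  scorer <- scorer %||% nblast_scorer_parametric()
  dps <- lapply(x, function(m) {
    if (inherits(m, "dotprops")) m else make_dotprops(m, k = k, step = step)
  })
  if (length(dps) == 0L) stop("empty collection")
  keys <- names(dps) %||% as.character(seq_along(dps))
  if (is.null(names(dps))) names(dps) <- keys
  n <- length(dps)
  selfs <- vapply(dps, function(d) nblast_pair(d, d, scorer, "raw",
                                               alpha_weighted), numeric(1))
  raw <- matrix(NA_real_, n, n, dimnames = list(keys, keys))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    raw[i, j] <- if (i == j) selfs[i] else
      tryCatch(nblast_pair(dps[[i]], dps[[j]], scorer, "raw", alpha_weighted),
               error = function(e) stop("nblast failed for pair (", keys[i],
                                        ", ", keys[j], "): ",
                                        conditionMessage(e), call. = FALSE))
  }
  norm <- raw / selfs  # row-wise self normalisation
  scores <- switch(normalisation,
                   raw = raw,
                   self = norm,
                   mean = (norm + t(norm)) / 2)
  structure(list(scores = scores, normalisation = normalisation),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d x %d (%s-normalised)\n", nrow(x$scores),
              ncol(x$scores), x$normalisation))
  invisible(x)
}

#' Hierarchically cluster an NBLAST score table
#'
#' Distance is `1 - mean score` clipped to `[0, 2]`; agglomeration uses
#' Ward linkage by default. The merge tree can be cut at a group count or
#' height and exported as Newick text.
#'
#' @param table a symmetric-normalised [nblast_all_by_all()] result (or a
#'   symmetric numeric matrix).
#' @param k number of clusters, or `h` cut height (one of the two).
#' @param h cut height.
#' @param method linkage passed to [stats::hclust()] (default
#'   `"ward.D2"`).
#' @return list of class `score_clustering`: `labels` (named integer
#'   vector), `hclust` (the merge tree) and `newick` (Newick text of the
#'   dendrogram).
#' @export
cluster_scores <- function(table, k = NULL, h = NULL, method = "ward.D2") {
  m <- if (inherits(table, "score_table")) table$scores else as.matrix(table)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    stop("score table must be symmetric (use mean-of-directions normalisation)")
  }
  if (!is.null(k) && (k < 1L || k > nrow(m))) stop("k must be in 1..N")
  if (nrow(m) == 1L) {
    return(structure(list(labels = stats::setNames(1L, rownames(m)),
                          hclust = NULL,
                          newick = paste0("(", rownames(m), ");")),
                     class = "score_clustering"))
  }
  dmat <- pmin(pmax(1 - m, 0), 2)
  diag(dmat) <- 0
  hc <- stats::hclust(stats::as.dist(dmat), method = method)
  labels <- if (!is.null(k) || !is.null(h)) {
    stats::cutree(hc, k = k, h = h)
  } else {
    stats::setNames(rep(1L, nrow(m)), rownames(m))
  }
  newick <- if (nrow(m) >= 3L) {
    ape::write.tree(ape::as.phylo(hc))
  } else {
    paste0("(", paste(rownames(m), collapse = ","), ");")
  }
  structure(list(labels = labels, hclust = hc, newick = newick),
            class = "score_clustering")
}

#' @export
print.score_clustering <- function(x, ...) {
  cat(sprintf("<score_clustering> %d members, %d cluster(s)\n",
              length(x$labels), length(unique(x$labels))))
  invisible(x)
}
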