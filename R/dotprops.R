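# Vector-cloud (dotprops) representation: each point carries the dominant
# principal direction of its k nearest neighbours and a colinearity
# weight alpha = (l1 - l2) / (l1 + l2 + l3) from the local covariance
# eigenvalues. Tangent sign is arbitrary; all scoring uses |dot|.

#' Build a dotprops vector cloud
#'
#' @param x a [neuron][build_neuron] or an N x 3 point matrix.
#' @param k neighbourhood size (self inclusive), `k >= 2`; must not exceed
#'   the number of points.
#' @param step optional resampling step applied to a neuron before
#'   conversion (see [resample()]).
#' @param unit unit label when `x` is a bare point matrix.
#' @return object of class `dotprops`: `points`, unit `vectors`, `alpha`,
#'   `k`, `unit`.
#' @export
make_dotprops <- function(x, k = 5L, step = NULL, unit = NULL) {
  if (is.neuron(x)) {
    if (!is.null(step)) x <- resample(x, step)
    pts <- neuron_xyz(x)
    unit <- x$unit
  } else {
    pts <- as_points3(x)
    unit <- unit %||% skt_options()$unit
  }
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (nrow(pts) < k) {
    stop(sprintf("need at least k = %d points, got %d", k, nrow(pts)))
  }
  nn <- RANN::nn2(pts, pts, k = k)
  vecs <- matrix(0, nrow(pts), 3L)
  alpha <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    nb <- pts[nn$nn.idx[i, ], , drop = FALSE]
    cv <- stats::cov(nb)
    if (!all(is.finite(cv)) || sum(diag(cv)) == 0) {
      stop("degenerate neighbourhood: coincident points at index ", i)
    }
    ev <- eigen(cv, symmetric = TRUE)
    vecs[i, ] <- ev$vectors[, 1]
    l <- pmax(ev$values, 0)
    alpha[i] <- (l[1] - l[2]) / sum(l)
  }
  structure(list(points = pts, vectors = vecs, alpha = alpha, k = k,
                 unit = unit),
            class = "dotprops")
}

#' @export
print.dotprops <- function(x, ...) {
  cat(sprintf("<dotprops> %d points (k = %d, %s), mean alpha %.3f\n",
              nrow(x$points), x$k, x$unit, mean(x$alpha)))
  invisible(x)
}

#' Align a point cloud or neuron by its principal axes
#'
#' Moves the soma (or centroid) to the origin and rotates so the
#' principal components lie along x, y, z in decreasing-variance order.
#' Sign convention: each axis is flipped so its coordinate skewness
#' (sum of cubes) is non-negative. Degenerate clouds (near-equal
#' variances, fewer than 3 non-collinear points) fall back to the
#' identity rotation with a warning.
#'
#' @param x a [neuron][build_neuron], dotprops or N x 3 point matrix.
#' @param tol relative eigenvalue-gap threshold below which the frame is
#'   declared degenerate.
#' @return the same type as `x`, aligned; `attr(, "rotation")` carries the
#'   3 x 3 rotation used.
#' @export
align_principal_axes <- function(x, tol = 1e-8) {
  pts <- if (is.neuron(x)) neuron_xyz(x)
         else if (inherits(x, "dotprops")) x$points
         else as_points3(x)
  origin <- if (is.neuron(x) && !is.null(x$soma_id)) {
    pts[match(x$soma_id, x$nodes$id), ]
  } else {
    colMeans(pts)
  }
  ctr <- sweep(pts, 2L, colMeans(pts))
  R <- diag(3)
  if (nrow(pts) >= 3L) {
    ev <- eigen(stats::cov(ctr), symmetric = TRUE)
    gaps <- abs(diff(ev$values))
    if (ev$values[1] <= 0 || any(gaps / ev$values[1] < tol)) {
      warning("degenerate principal axes; identity rotation used")
    } else {
      R <- ev$vectors  # columns = principal directions, variance-ordered
      rot <- ctr %*% R
      for (d in 1:3) if (sum(rot[, d]^3) < 0) R[, d] <- -R[, d]
    }
  } else {
    warning("fewer than 3 points; identity rotation used")
  }
  t_align <- affine_transform(cbind(t(R), -t(R) %*% origin))
  out <- apply_transform(t_align, x)
  attr(out, "rotation") <- t(R)
  out
}
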