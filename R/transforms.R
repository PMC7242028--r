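# Transforms of 3-space: affine, thin-plate spline (kernel U(r) = r, the
# 3D biharmonic fundamental solution), axis flips, sequences, and
# numerically inverted maps.

new_transform <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = c(paste0(kind, "_transform"), "transform"))
}

#' @export
print.transform <- function(x, ...) {
  cat(sprintf("<transform:%s>\n", x$kind))
  invisible(x)
}

#' Affine transform from a 3 x 4 matrix
#'
#' Maps `x` to `A %*% x + b` where the matrix is `[A | b]`.
#'
#' @param matrix 3 x 4 numeric matrix.
#' @return a `transform`.
#' @export
affine_transform <- function(matrix) {
  matrix <- base::matrix(as.numeric(matrix), 3L, 4L)
  if (any(!is.finite(matrix))) stop("non-finite affine parameters")
  new_transform("affine", list(matrix = matrix))
}

#' Identity transform
#' @return a `transform`.
#' @export
identity_transform <- function() affine_transform(cbind(diag(3), 0))

#' Axis-flip transform
#'
#' Involution mapping the chosen coordinate `v` to `lo + hi - v`.
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param lo,hi extent of the flipped axis (typically the template-space
#'   bounding box on that axis).
#' @return a `transform`.
#' @export
flip_transform <- function(axis = c("x", "y", "z"), lo, hi) {
  axis <- match.arg(axis)
  new_transform("flip", list(axis = match(axis, c("x", "y", "z")),
                             lo = as.numeric(lo), hi = as.numeric(hi)))
}

#' Compose transforms into a sequence
#'
#' @param ... transforms, applied in the order given (first argument
#'   first).
#' @return a `transform`.
#' @export
sequence_transform <- function(...) {
  ts <- list(...)
  if (length(ts) == 1L && is.list(ts[[1]]) && !inherits(ts[[1]], "transform")) {
    ts <- ts[[1]]
  }
  if (length(ts) == 0L) stop("empty transform sequence")
  stopifnot(all(vapply(ts, inherits, logical(1), "transform")))
  new_transform("sequence", list(transforms = ts))
}

#' Fit a least-squares affine transform to landmark pairs
#'
#' Minimises the sum of squared residuals `||A s + b - t||^2`; exact when
#' the pairs are affinely consistent.
#'
#' @param landmarks a [landmark_pairs()] with `N >= 4` non-coplanar source
#'   points.
#' @return an affine `transform`; `attr(, "rmse")` holds the fit residual.
#' @export
fit_affine <- function(landmarks) {
  s <- landmarks$source; t <- landmarks$target
  if (nrow(s) < 4L) stop("need at least 4 landmark pairs")
  X <- cbind(s, 1)
  qx <- qr(X)
  if (qx$rank < 4L) stop("degenerate source landmarks (coplanar or collinear)")
  B <- qr.coef(qx, t)                      # 4 x 3
  M <- t(B)[, c(1:3, 4), drop = FALSE]     # 3 x 4 [A | b]
  tr <- affine_transform(M)
  res <- X %*% B - t
  attr(tr, "rmse") <- sqrt(mean(rowSums(res^2)))
  tr
}

#' Fit a 3D thin-plate-spline transform to landmark pairs
#'
#' Radial kernel `U(r) = r` plus an affine part; with `lambda = 0` the
#' spline interpolates every landmark exactly.
#'
#' @param landmarks a [landmark_pairs()] with `N >= 5` distinct source
#'   points.
#' @param lambda non-negative smoothing parameter (0 = pure
#'   interpolation).
#' @return a tps `transform` carrying the control points, warp weights and
#'   affine part.
#' @export
fit_tps <- function(landmarks, lambda = 0) {
  s <- landmarks$source; tg <- landmarks$target
  n <- nrow(s)
  if (n < 5L) stop("need at least 5 landmark pairs for a 3D TPS")
  if (lambda < 0) stop("lambda must be non-negative")
  K <- as.matrix(stats::dist(s))           # U(r) = r
  P <- cbind(1, s)
  L <- rbind(cbind(K + diag(lambda, n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(tg, matrix(0, 4, 3))
  coefs <- tryCatch(solve(L, rhs), error = function(e) {
    stop("singular TPS system (duplicate or degenerate source points)")
  })
  new_transform("tps", list(control = s,
                            weights = coefs[seq_len(n), , drop = FALSE],
                            affine = coefs[n + 1:4, , drop = FALSE],
                            lambda = lambda))
}

#' Numerically invert a transform
#'
#' Solves `t(y) = x` per query point with a damped Newton iteration
#' (numerical Jacobian, started at `y = x`). Affine transforms
#' short-circuit to the closed-form inverse and flips to themselves.
#'
#' @param t a `transform`, locally invertible near the queried points.
#' @param tolerance convergence requirement on `||t(y) - x||` (length
#'   units).
#' @param max_iter iteration cap per point; non-convergence is an error
#'   naming the offending point.
#' @return a `transform`.
#' @export
invert_numeric <- function(t, tolerance = 1e-6, max_iter = 100L) {
  if (t$kind == "affine") {
    A <- t$matrix[, 1:3]; b <- t$matrix[, 4]
    Ai <- solve(A)
    return(affine_transform(cbind(Ai, -Ai %*% b)))
  }
  if (t$kind == "flip") return(t)
  if (t$kind == "numeric_inverse") return(t$wrapped)
  if (t$kind == "sequence") {
    inv <- lapply(rev(t$transforms), invert_numeric,
                  tolerance = tolerance, max_iter = max_iter)
    return(sequence_transform(inv))
  }
  new_transform("numeric_inverse",
                list(wrapped = t, tolerance = tolerance,
                     max_iter = as.integer(max_iter)))
}

# ---- point mapping ----

tf_points <- function(t, pts) {
  pts <- as_points3(pts)
  out <- switch(
    t$kind,
    affine = {
      pts %*% t(t$matrix[, 1:3]) + rep(t$matrix[, 4], each = nrow(pts))
    },
    flip = {
      pts[, t$axis] <- t$lo + t$hi - pts[, t$axis]
      pts
    },
    tps = {
      # distances from queries to control points
      D2 <- outer(rowSums(pts^2), rowSums(t$control^2), "+") -
        2 * pts %*% t(t$control)
      D <- sqrt(pmax(D2, 0))
      cbind(1, pts) %*% t$affine + D %*% t$weights
    },
    sequence = {
      for (tt in t$transforms) pts <- tf_points(tt, pts)
      pts
    },
    numeric_inverse = .tf_numeric_inverse(t, pts),
    stop("unknown transform kind: ", t$kind)
  )
  bad <- which(!is.finite(out[, 1] + out[, 2] + out[, 3]))
  if (length(bad)) stop("transform undefined at input point index ", bad[1])
  out
}

.tf_numeric_inverse <- function(t, pts) {
  fwd <- t$wrapped
  tol <- t$tolerance
  maxit <- t$max_iter
  h <- 1e-4 * max(1, max(abs(pts)))
  out <- matrix(NA_real_, nrow(pts), 3L)
  for (i in seq_len(nrow(pts))) {
    x <- pts[i, ]
    y <- x
    r <- tf_points(fwd, rbind(y))[1, ] - x
    ok <- FALSE
    for (iter in seq_len(maxit)) {
      if (sqrt(sum(r^2)) < tol) { ok <- TRUE; break }
      # numerical Jacobian, central differences
      J <- matrix(0, 3, 3)
      for (d in 1:3) {
        e <- c(0, 0, 0); e[d] <- h
        J[, d] <- (tf_points(fwd, rbind(y + e))[1, ] -
                     tf_points(fwd, rbind(y - e))[1, ]) / (2 * h)
      }
      step <- tryCatch(solve(J, r), error = function(e) r)  # gradient fallback
      lam <- 1
      repeat {
        y2 <- y - lam * step
        r2 <- tf_points(fwd, rbind(y2))[1, ] - x
        if (sum(r2^2) < sum(r^2) || lam < 1e-6) break
        lam <- lam / 2
      }
      y <- y - lam * step
      r <- tf_points(fwd, rbind(y))[1, ] - x
    }
    if (!ok && sqrt(sum(r^2)) >= tol) {
      stop(sprintf("numeric inversion did not converge at point %d (%.3g, %.3g, %.3g)",
                   i, x[1], x[2], x[3]))
    }
    out[i, ] <- y
  }
  out
}

#' Apply a transform to points, a neuron, dotprops or a mesh
#'
#' Positions (including connector positions) are mapped; neuron topology,
#' ids and tags, and mesh faces are unchanged. Dotprops tangent vectors
#' are re-derived by mapping `point + eps * vector` and renormalising
#' (`eps = 0.1` units).
#'
#' @param t a `transform`.
#' @param data N x 3 matrix, [neuron][build_neuron], dotprops or
#'   [trimesh()].
#' @return the same type as `data`.
#' @export
apply_transform <- function(t, data) {
  stopifnot(inherits(t, "transform"))
  if (is.neuron(data)) {
    xyz <- tf_points(t, neuron_xyz(data))
    data$nodes$x <- xyz[, 1]; data$nodes$y <- xyz[, 2]; data$nodes$z <- xyz[, 3]
    if (nrow(data$connectors)) {
      cxyz <- tf_points(t, as.matrix(data$connectors[, c("x", "y", "z")]))
      data$connectors$x <- cxyz[, 1]
      data$connectors$y <- cxyz[, 2]
      data$connectors$z <- cxyz[, 3]
    }
    return(data)
  }
  if (inherits(data, "dotprops")) {
    eps <- 0.1
    p0 <- tf_points(t, data$points)
    p1 <- tf_points(t, data$points + eps * data$vectors)
    v <- p1 - p0
    nv <- row_norms(v)
    if (any(nv == 0)) stop("transform collapsed a tangent vector")
    data$points <- p0
    data$vectors <- v / nv
    return(data)
  }
  if (inherits(data, "trimesh")) {
    data$vertices <- tf_points(t, data$vertices)
    return(data)
  }
  tf_points(t, data)
}
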