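# 3D computational-geometry primitives written for this package:
# an incremental convex hull and a Bowyer-Watson Delaunay
# tetrahedralisation (used for alpha shapes). Sizes here are modest
# (hundreds of points), so clarity is preferred over asymptotics.

# Incremental convex hull. Returns list(faces = K x 3 index matrix into
# pts rows, oriented outward). Degenerate (coplanar) input is an error.
convex_hull_3d <- function(pts) {
  pts <- as_points3(pts)
  n <- nrow(pts)
  if (n < 4L) stop("degenerate: need at least 4 points for a 3D hull")
  scale <- max(apply(pts, 2L, function(c) diff(range(c))), 1e-12)
  eps <- 1e-10 * scale

  # initial simplex from extreme points
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (sqrt(sum((pts[i1, ] - pts[i2, ])^2)) < eps) {
    stop("degenerate: points nearly coincident")
  }
  u <- pts[i2, ] - pts[i1, ]
  dl <- row_norms(cross3(sweep(pts, 2L, pts[i1, ]), u)) / sqrt(sum(u^2))
  i3 <- which.max(dl)
  if (dl[i3] < eps) stop("degenerate: points nearly collinear")
  nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])[1, ]
  dp <- abs(as.vector(sweep(pts, 2L, pts[i1, ]) %*% nrm)) / sqrt(sum(nrm^2))
  i4 <- which.max(dp)
  if (dp[i4] < eps) stop("degenerate: points nearly coplanar")

  interior <- colMeans(pts[c(i1, i2, i3, i4), , drop = FALSE])
  orient_face <- function(f) {
    nn <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])[1, ]
    if (sum(nn * (interior - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- lapply(list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4)),
                  orient_face)

  face_normal <- function(f) {
    cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])[1, ]
  }
  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    vis <- vapply(faces, function(f) {
      sum(face_normal(f) * (pts[p, ] - pts[f[1], ])) > eps * scale
    }, logical(1))
    if (!any(vis)) next  # inside or on the hull
    # horizon: directed edges of visible faces whose reverse is not visible
    vis_faces <- faces[vis]
    edges <- do.call(rbind, lapply(vis_faces, function(f) {
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])
    }))
    keys <- paste(edges[, 1], edges[, 2])
    rkeys <- paste(edges[, 2], edges[, 1])
    # an edge is on the horizon iff its reverse is not an edge of another
    # visible face (consistent orientation: interior edges appear twice,
    # once per direction)
    horizon <- edges[!(rkeys %in% keys), , drop = FALSE]
    faces <- faces[!vis]
    for (e in seq_len(nrow(horizon))) {
      faces[[length(faces) + 1L]] <-
        orient_face(c(horizon[e, 1], horizon[e, 2], p))
    }
  }
  fm <- do.call(rbind, faces)
  # sanity: all points within eps outside any face plane
  for (f in faces) {
    nn <- face_normal(f)
    mx <- max(as.vector(sweep(pts, 2L, pts[f[1], ]) %*% nn)) / max(sqrt(sum(nn^2)), 1e-300)
    if (mx > 1e-6 * scale) stop("convex hull construction failed (numerical)")
  }
  list(faces = fm)
}

# Bowyer-Watson 3D Delaunay tetrahedralisation. Input is deterministically
# jittered (relative 1e-8) to break cospherical degeneracies; returned
# circumradii refer to the jittered coordinates, tet vertex indices refer
# to the original points. Returns list(tets = T x 4 index matrix,
# circumradius = length-T vector).
delaunay_3d <- function(pts, jitter_seed = 1L) {
  pts <- as_points3(pts)
  n <- nrow(pts)
  if (n < 4L) stop("degenerate: need at least 4 points")
  scale <- max(apply(pts, 2L, function(c) diff(range(c))), 1e-12)
  p <- pts + with_seed(jitter_seed,
                       matrix(stats::runif(3L * n, -1, 1), n, 3L)) * 1e-8 * scale

  # super-tetrahedron far outside the data: the farther it is, the closer
  # the data-only tets come to tiling the full convex hull (near-hull
  # slivers otherwise attach to super vertices and get discarded)
  ctr <- colMeans(p)
  R <- max(row_norms(sweep(p, 2L, ctr))) * 1e5 + scale
  sup <- rbind(ctr + c(0, 0, 4) * R,
               ctr + c(-3, -2, -2) * R,
               ctr + c(3, -2, -2) * R,
               ctr + c(0, 3.5, -2) * R)
  P <- rbind(p, sup)
  sup_idx <- n + 1:4

  # circumcenter: solve (Pk - P1) . c0 = |Pk - P1|^2 / 2, center = P1 + c0
  circum <- function(tet) {
    A <- P[tet[2:4], , drop = FALSE] - rep(P[tet[1], ], each = 3L)
    b <- 0.5 * rowSums(A * A)
    c0 <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(c0)) return(c(NA, NA, NA, Inf))
    c(P[tet[1], ] + c0, sqrt(sum(c0 * c0)))
  }
  tets <- list(sort(sup_idx))
  meta <- list(circum(sort(sup_idx)))  # (cx, cy, cz, r)

  for (ip in seq_len(n)) {
    pt <- P[ip, ]
    bad <- vapply(seq_along(tets), function(t) {
      m <- meta[[t]]
      if (!is.finite(m[4])) return(TRUE)  # flat tet: treat as always invalid
      sum((pt - m[1:3])^2) <= m[4]^2 * (1 + 1e-12)
    }, logical(1))
    if (!any(bad)) stop("Delaunay insertion failed (numerical)")
    bad_tets <- tets[bad]
    # cavity boundary: faces appearing exactly once among bad tets
    faces <- do.call(rbind, lapply(bad_tets, function(t) {
      rbind(t[-1], t[-2], t[-3], t[-4])
    }))
    faces_sorted <- t(apply(faces, 1L, sort))
    key <- paste(faces_sorted[, 1], faces_sorted[, 2], faces_sorted[, 3])
    once <- key %in% names(which(table(key) == 1L))
    boundary <- faces_sorted[once, , drop = FALSE]
    tets <- tets[!bad]
    meta <- meta[!bad]
    for (f in seq_len(nrow(boundary))) {
      tet <- sort(c(boundary[f, ], ip))
      # degenerate (flat) tets are kept with infinite circumradius: they are
      # invalidated and retriangulated by any later insertion, and dropped
      # from alpha filtering at the end
      tets[[length(tets) + 1L]] <- tet
      meta[[length(meta) + 1L]] <- circum(tet)
    }
  }
  keep <- vapply(tets, function(t) all(t <= n), logical(1))
  tets <- tets[keep]
  meta <- meta[keep]
  if (length(tets) == 0L) stop("degenerate: no interior tetrahedra")
  list(tets = do.call(rbind, tets),
       circumradius = vapply(meta, function(m) m[4], numeric(1)))
}

# boundary mesh of a set of tets: faces used by exactly one tet, oriented
# outward from the owning tet
tet_boundary_mesh <- function(pts, tets, unit = NULL) {
  faces <- do.call(rbind, lapply(seq_len(nrow(tets)), function(i) {
    t <- tets[i, ]
    cbind(rbind(t[-1], t[-2], t[-3], t[-4]), i)
  }))
  fs <- t(apply(faces[, 1:3, drop = FALSE], 1L, sort))
  key <- paste(fs[, 1], fs[, 2], fs[, 3])
  once <- key %in% names(which(table(key) == 1L))
  bf <- faces[once, , drop = FALSE]
  out <- matrix(0L, nrow(bf), 3L)
  for (i in seq_len(nrow(bf))) {
    f <- bf[i, 1:3]
    owner <- tets[bf[i, 4], ]
    opp <- setdiff(owner, f)
    nn <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])[1, ]
    if (sum(nn * (pts[opp, ] - pts[f[1], ])) > 0) f <- f[c(1, 3, 2)]
    out[i, ] <- f
  }
  trimesh(pts, out, unit = unit)
}
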