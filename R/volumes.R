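# Mesh-based volumetric analysis: volumes, point-in-mesh tests, in-volume
# pruning, bounding volumes, overlap and potential-synapse scores.

region_faces <- function(mesh, region = NULL) {
  if (is.null(region)) return(mesh$faces)
  if (!region %in% names(mesh$regions)) stop("unknown region: ", region)
  mesh$faces[mesh$regions[[region]], , drop = FALSE]
}

# closed + consistently oriented: every undirected edge used exactly twice,
# in opposite directions
assert_closed_mesh <- function(faces) {
  if (nrow(faces) == 0L) stop("open mesh: no faces")
  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  keys <- paste(edges[, 1], edges[, 2])
  rkeys <- paste(edges[, 2], edges[, 1])
  tab <- table(keys)
  if (any(tab > 1L)) stop("inconsistent orientation: repeated directed edge")
  if (!all(keys %in% rkeys)) stop("open mesh: boundary edge found")
  invisible(TRUE)
}

#' Volume enclosed by a mesh region
#'
#' Sum of signed tetrahedron volumes `det(v1, v2, v3) / 6` over faces.
#' The region must be closed and consistently oriented.
#'
#' @param mesh a [trimesh()].
#' @param region optional region name (default: whole mesh).
#' @return enclosed volume (units cubed).
#' @export
mesh_volume <- function(mesh, region = NULL) {
  f <- region_faces(mesh, region)
  assert_closed_mesh(f)
  v <- mesh$vertices
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  abs(sum(rowSums(a * cross3(b, cc))) / 6)
}

#' Which points lie inside a mesh region?
#'
#' Ray-parity test with a fixed ray direction; near-degenerate hits
#' (grazing an edge or vertex) are retried with deterministically
#' jittered rays. Points on the surface count as inside.
#'
#' @param points N x 3 matrix.
#' @param mesh a [trimesh()]; the queried region must be closed.
#' @param region optional region name.
#' @param tol surface/degeneracy tolerance, relative to the mesh scale.
#' @return logical vector of length N.
#' @export
points_inside <- function(points, mesh, region = NULL, tol = 1e-9) {
  pts <- as_points3(points)
  f <- region_faces(mesh, region)
  assert_closed_mesh(f)
  v <- mesh$vertices
  scale <- max(apply(v, 2L, function(c) diff(range(c))), 1e-12)
  dirs <- rbind(c(0.28108, 0.54773, 0.78806),
                c(-0.61311, 0.33962, 0.71335),
                c(0.80171, -0.46147, 0.37988),
                c(0.13729, 0.86470, -0.48319),
                c(-0.35792, -0.62141, 0.69704),
                c(0.92341, 0.21703, -0.31632),
                c(-0.15874, 0.72839, 0.66651),
                c(0.50331, -0.80113, 0.32341))
  dirs <- dirs / row_norms(dirs)
  inside <- logical(nrow(pts))
  pending <- seq_len(nrow(pts))
  for (trial in seq_len(nrow(dirs))) {
    res <- .ray_parity(pts[pending, , drop = FALSE], v, f, dirs[trial, ],
                       tol * scale)
    done <- !res$suspect
    inside[pending[done]] <- res$inside[done]
    pending <- pending[!done]
    if (length(pending) == 0L) break
  }
  if (length(pending)) {
    stop("ray-parity test degenerate for point index ", pending[1],
         " after all jitter retries")
  }
  inside
}

# vectorised Moller-Trumbore over points, one face at a time.
# returns inside (logical: odd crossings or on surface) and suspect flags.
.ray_parity <- function(pts, v, f, dir, eps) {
  n <- nrow(pts)
  hits <- integer(n)
  on_surface <- logical(n)
  suspect <- logical(n)
  btol <- 1e-9
  for (i in seq_len(nrow(f))) {
    v0 <- v[f[i, 1], ]; v1 <- v[f[i, 2], ]; v2 <- v[f[i, 3], ]
    e1 <- v1 - v0; e2 <- v2 - v0
    h <- c(dir[2] * e2[3] - dir[3] * e2[2],
           dir[3] * e2[1] - dir[1] * e2[3],
           dir[1] * e2[2] - dir[2] * e2[1])
    a <- sum(e1 * h)
    s <- sweep(pts, 2L, v0)
    if (abs(a) < 1e-12 * max(sqrt(sum(e1^2)) * sqrt(sum(e2^2)), 1e-300)) {
      # ray parallel to face: suspect any point whose projection is near the
      # face plane (its parity could depend on this face)
      nn <- cross3(e1, e2)[1, ]
      dist_plane <- abs(as.vector(s %*% nn)) / max(sqrt(sum(nn^2)), 1e-300)
      suspect <- suspect | (dist_plane < eps * 10)
      next
    }
    fct <- 1 / a
    u <- fct * as.vector(s %*% h)
    q <- cross3(s, matrix(e1, 1))
    vv <- fct * as.vector(q %*% dir)
    t <- fct * as.vector(q %*% e2)
    valid <- u >= 0 & u <= 1 & vv >= 0 & (u + vv) <= 1
    on_this <- valid & abs(t) < eps
    on_surface <- on_surface | on_this
    cross_hit <- valid & t > eps
    hits <- hits + cross_hit
    near_edge <- (u > -btol & u < btol) | (vv > -btol & vv < btol) |
      (u + vv > 1 - btol & u + vv < 1 + btol)
    suspect <- suspect | (near_edge & t > eps & u > -btol & vv > -btol &
                            (u + vv) < 1 + btol)
  }
  list(inside = on_surface | (hits %% 2L == 1L), suspect = suspect & !on_surface)
}

#' Prune a neuron to the cable inside (or outside) a volume
#'
#' Vertex-based: nodes on the losing side are removed and the remaining
#' forest re-validated (children of removed nodes become roots);
#' connectors on removed nodes are dropped and counted in the log.
#' Resample first to bound the cable error at the mesh boundary.
#'
#' @param neuron a [neuron][build_neuron] in the mesh's unit.
#' @param mesh a closed [trimesh()].
#' @param keep `"inside"` or `"outside"`.
#' @param region optional region name.
#' @return the pruned `neuron`.
#' @export
prune_in_volume <- function(neuron, mesh, keep = c("inside", "outside"),
                            region = NULL) {
  keep <- match.arg(keep)
  check_same_unit(neuron$unit, mesh$unit)
  ins <- points_inside(neuron_xyz(neuron), mesh, region)
  sel <- if (keep == "inside") ins else !ins
  if (!any(sel)) {
    stop(sprintf("empty result: 0 of %d nodes are %s the volume",
                 length(sel), keep))
  }
  subset_neuron_rows(neuron, sel)
}

#' Fit a bounding volume to a point cloud
#'
#' Convex hull, or an alpha shape (the boundary of the Delaunay
#' tetrahedra with circumradius below `alpha`; `alpha = Inf` recovers the
#' hull). The returned mesh is closed and outward-oriented;
#' `attr(, "n_components")` counts connected shell components.
#'
#' @param points N x 3 matrix (N >= 4, not coplanar).
#' @param method `"convex_hull"` or `"alpha_shape"`.
#' @param alpha radius threshold, length units (alpha shapes only).
#' @param unit unit label.
#' @return a [trimesh()].
#' @export
fit_bounding_volume <- function(points, method = c("convex_hull", "alpha_shape"),
                                alpha = Inf, unit = NULL) {
  method <- match.arg(method)
  pts <- as_points3(points)
  if (method == "convex_hull") {
    hull <- convex_hull_3d(pts)
    mesh <- trimesh(pts, hull$faces, unit = unit)
  } else {
    stopifnot(alpha > 0)
    dt <- delaunay_3d(pts)
    keep <- dt$circumradius < alpha
    if (!any(keep)) stop("alpha too small: no tetrahedra retained")
    mesh <- tet_boundary_mesh(pts, dt$tets[keep, , drop = FALSE], unit = unit)
  }
  # connected shell components via shared edges
  f <- mesh$faces
  if (nrow(f)) {
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    fid <- rep(seq_len(nrow(f)), 3L)
    grp <- split(fid, ekey)
    el <- do.call(rbind, lapply(grp, function(g) {
      if (length(g) < 2L) return(NULL)
      cbind(g[1], g[-1])
    }))
    if (is.null(el)) {
      attr(mesh, "n_components") <- nrow(f)
    } else {
      g <- igraph::graph_from_edgelist(matrix(as.character(el), ncol = 2L),
                                       directed = FALSE)
      ncomp <- igraph::components(g)$no +
        sum(!(as.character(seq_len(nrow(f))) %in% igraph::V(g)$name))
      attr(mesh, "n_components") <- ncomp
    }
  }
  mesh
}

#' Proximity overlap score between two structures
#'
#' `sum over points a of A of exp(-d(a, B)^2 / (2 delta^2))` with `d` the
#' nearest-neighbour distance; deliberately asymmetric in (A, B).
#'
#' @param A,B neurons or N x 3 point matrices in the same unit.
#' @param delta proximity scale (> 0), length units.
#' @return numeric score (equals `nrow(A)` when `A == B`).
#' @export
overlap_score <- function(A, B, delta) {
  stopifnot(delta > 0)
  pa <- if (is.neuron(A)) neuron_xyz(A) else as_points3(A)
  pb <- if (is.neuron(B)) neuron_xyz(B) else as_points3(B)
  if (is.neuron(A) && is.neuron(B)) check_same_unit(A$unit, B$unit)
  if (nrow(pa) == 0L || nrow(pb) == 0L) stop("empty input")
  d <- RANN::nn2(pb, pa, k = 1L)$nn.dists[, 1]
  sum(exp(-d^2 / (2 * delta^2)))
}

#' Potential synapses between two neurons
#'
#' Both skeletons are resampled to edge length at most `s/2`; over all
#' edge pairs (one from each neuron) whose midpoints lie within `s`,
#' reports the close-pair count and the approach-angle-weighted sum
#' `sum(l_i * l_j * sin(theta_ij))` (units length squared). Symmetric in
#' the two neurons. Reported unnormalised: calibrate against your own
#' data.
#'
#' @param A,B [neuron][build_neuron] objects in the same unit.
#' @param s proximity threshold (> 0), length units.
#' @return list with `close_pair_count` and `angle_weighted_sum`.
#' @export
potential_synapses <- function(A, B, s) {
  stopifnot(s > 0)
  check_same_unit(A$unit, B$unit)
  seg_table <- function(n) {
    n <- resample(n, s / 2)
    idx <- match(n$nodes$parent_id, n$nodes$id)
    ok <- which(!is.na(idx))
    if (length(ok) == 0L) stop("empty neuron: no edges")
    xyz <- neuron_xyz(n)
    p1 <- xyz[ok, , drop = FALSE]
    p2 <- xyz[idx[ok], , drop = FALSE]
    list(mid = (p1 + p2) / 2, dir = p2 - p1, len = row_norms(p2 - p1))
  }
  sa <- seg_table(A)
  sb <- seg_table(B)
  count <- 0L
  wsum <- 0
  # pairs within s via radius search from A midpoints into B midpoints
  kmax <- nrow(sb$mid)
  nn <- RANN::nn2(sb$mid, sa$mid, k = kmax, searchtype = "radius", radius = s)
  ua <- sa$dir / pmax(sa$len, 1e-300)
  ub <- sb$dir / pmax(sb$len, 1e-300)
  for (i in seq_len(nrow(sa$mid))) {
    js <- nn$nn.idx[i, ]
    js <- js[js > 0L]
    if (length(js) == 0L) next
    count <- count + length(js)
    cosang <- pmin(abs(as.vector(ub[js, , drop = FALSE] %*% ua[i, ])), 1)
    sinang <- sqrt(pmax(1 - cosang^2, 0))
    wsum <- wsum + sum(sa$len[i] * sb$len[js] * sinang)
  }
  list(close_pair_count = count, angle_weighted_sum = wsum)
}
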