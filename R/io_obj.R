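# Wavefront OBJ (v/f subset) for neuropil and template surfaces.
# Polygonal faces are fan-triangulated from the first vertex; vt/vn and
# material records are ignored. Face indices are 1-based on disk and kept
# 1-based internally (the R indexing convention).

#' Construct a triangle mesh
#'
#' @param vertices M x 3 numeric matrix.
#' @param faces K x 3 integer matrix of 1-based vertex indices.
#' @param regions named list of face-index vectors marking named
#'   subregions (e.g. neuropils); `NULL` means the whole mesh.
#' @param unit length-unit label.
#' @return an object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, regions = list(), unit = NULL) {
  vertices <- as_points3(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face index out of range")
  }
  if (length(regions)) {
    stopifnot(!is.null(names(regions)))
    regions <- lapply(regions, as.integer)
    if (any(vapply(regions, function(v) any(v < 1L | v > nrow(faces)), logical(1)))) {
      stop("region face index out of range")
    }
  }
  structure(list(vertices = vertices, faces = faces, regions = regions,
                 unit = unit %||% skt_options()$unit),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d faces%s\n", nrow(x$vertices),
              nrow(x$faces),
              if (length(x$regions)) paste0(", regions: ",
                                            paste(names(x$regions), collapse = ", "))
              else ""))
  invisible(x)
}

#' Read a Wavefront OBJ mesh
#'
#' Parses `v` and `f` records (named groups `g`/`o` become regions);
#' `vt`/`vn`/material records are ignored. Faces with more than three
#' vertices are fan-triangulated from the first vertex.
#'
#' @param file path or connection.
#' @param unit length-unit label.
#' @return a [trimesh()].
#' @export
read_obj_mesh <- function(file, unit = NULL) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines)]
  verts <- list(); faces <- list()
  regions <- list(); current_region <- NULL
  for (ln in lines) {
    tok <- strsplit(ln, "\\s+")[[1]]
    key <- tok[1]
    if (key == "v") {
      if (length(tok) < 4L) stop("malformed vertex record: ", ln)
      verts[[length(verts) + 1L]] <- as.numeric(tok[2:4])
    } else if (key == "f") {
      if (length(tok) < 4L) stop("non-polygonal face record: ", ln)
      idx <- as.integer(sub("/.*$", "", tok[-1]))
      if (anyNA(idx)) stop("malformed face record: ", ln)
      for (j in seq_len(length(idx) - 2L)) {
        faces[[length(faces) + 1L]] <- c(idx[1], idx[j + 1L], idx[j + 2L])
        if (!is.null(current_region)) {
          regions[[current_region]] <- c(regions[[current_region]], length(faces))
        }
      }
    } else if (key %in% c("g", "o") && length(tok) > 1L) {
      current_region <- tok[2]
      if (is.null(regions[[current_region]])) regions[[current_region]] <- integer(0)
    }
    # vt, vn, vp, mtllib, usemtl, s, comments: ignored
  }
  if (length(verts) == 0L) stop("no vertices in OBJ file")
  v <- do.call(rbind, verts)
  f <- if (length(faces)) do.call(rbind, faces) else matrix(integer(), 0, 3)
  if (nrow(f) && (min(f) < 1L || max(f) > nrow(v))) stop("face index out of range")
  trimesh(v, f, regions, unit)
}

#' Write a trimesh as Wavefront OBJ
#'
#' @param mesh a [trimesh()].
#' @param file path; if `NULL` the lines are returned.
#' @return invisibly, the character vector of lines.
#' @export
write_obj_mesh <- function(mesh, file = NULL) {
  out <- c("# OBJ written by skeletoolkit",
           sprintf("v %.17g %.17g %.17g",
                   mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]))
  f <- mesh$faces
  if (length(mesh$regions)) {
    # emit faces grouped by region, unassigned faces first
    assigned <- sort(unique(unlist(mesh$regions)))
    rest <- setdiff(seq_len(nrow(f)), assigned)
    if (length(rest)) out <- c(out, sprintf("f %d %d %d", f[rest, 1], f[rest, 2], f[rest, 3]))
    for (rn in names(mesh$regions)) {
      ri <- mesh$regions[[rn]]
      out <- c(out, paste("g", rn),
               sprintf("f %d %d %d", f[ri, 1], f[ri, 2], f[ri, 3]))
    }
  } else if (nrow(f)) {
    out <- c(out, sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  }
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
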