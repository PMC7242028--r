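# Landmark-pair CSV and NBLAST scoring-matrix TSV.

#' Construct a landmark-pair set
#'
#' @param source,target N x 3 matrices of corresponding positions.
#' @param names optional character vector of N labels.
#' @param unit length-unit label.
#' @return object of class `landmark_pairs`.
#' @export
landmark_pairs <- function(source, target, names = NULL, unit = NULL) {
  source <- as_points3(source)
  target <- as_points3(target)
  if (nrow(source) < 1L || nrow(source) != nrow(target)) {
    stop("source and target must be aligned with N >= 1 rows")
  }
  if (!is.null(names) && length(names) != nrow(source)) {
    stop("names must have one entry per landmark")
  }
  # duplicate source points (within 1e-9 of unit scale) are rejected
  if (nrow(source) > 1L) {
    o <- do.call(order, as.data.frame(source))
    s <- source[o, , drop = FALSE]
    dup <- rowSums(abs(diff(s))) < 1e-9
    if (any(dup)) stop("duplicate source points")
  }
  structure(list(source = source, target = target, names = names,
                 unit = unit %||% skt_options()$unit),
            class = "landmark_pairs")
}

#' @export
print.landmark_pairs <- function(x, ...) {
  cat(sprintf("<landmark_pairs> N = %d (%s)\n", nrow(x$source), x$unit))
  invisible(x)
}

#' Read landmark pairs from CSV
#'
#' Dialect: a header row, then one row per pair with columns
#' `x1,y1,z1,x2,y2,z2` (source then target), optionally preceded by a
#' `name` column.
#'
#' @param file path or connection.
#' @param unit length-unit label.
#' @return a [landmark_pairs()].
#' @export
read_landmarks_csv <- function(file, unit = NULL) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  cols <- c("x1", "y1", "z1", "x2", "y2", "z2")
  if (!all(cols %in% names(df))) {
    stop("landmark CSV must have columns x1,y1,z1,x2,y2,z2 (optional name)")
  }
  extra <- setdiff(names(df), c("name", cols))
  if (length(extra)) stop("unexpected landmark CSV column(s): ",
                          paste(extra, collapse = ", "))
  num <- as.matrix(df[, cols])
  if (!is.numeric(num) || any(!is.finite(num))) stop("non-numeric coordinates")
  landmark_pairs(num[, 1:3, drop = FALSE], num[, 4:6, drop = FALSE],
                 names = df$name, unit = unit)
}

#' Write landmark pairs as CSV
#' @param lm a [landmark_pairs()].
#' @param file path; if `NULL` lines are returned.
#' @return invisibly, the lines written.
#' @export
write_landmarks_csv <- function(lm, file = NULL) {
  num <- cbind(lm$source, lm$target)
  body <- apply(num, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  if (!is.null(lm$names)) {
    hdr <- "name,x1,y1,z1,x2,y2,z2"
    body <- paste(lm$names, body, sep = ",")
  } else {
    hdr <- "x1,y1,z1,x2,y2,z2"
  }
  out <- c(hdr, body)
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' Construct an NBLAST scoring matrix
#'
#' Log-score lookup table over (nearest-neighbour distance, absolute
#' tangent dot product) bins. Out-of-range values clamp to the edge bins.
#'
#' @param distance_breaks strictly ascending distance bin edges (length
#'   units).
#' @param dot_breaks strictly ascending dot-product bin edges in `[0, 1]`.
#' @param scores matrix of finite scores, one row per distance bin and one
#'   column per dot bin.
#' @return object of class `scoring_matrix`.
#' @export
scoring_matrix <- function(distance_breaks, dot_breaks, scores) {
  distance_breaks <- as.numeric(distance_breaks)
  dot_breaks <- as.numeric(dot_breaks)
  scores <- as.matrix(scores)
  if (length(distance_breaks) < 2L || any(diff(distance_breaks) <= 0)) {
    stop("distance bin edges must be strictly ascending")
  }
  if (length(dot_breaks) < 2L || any(diff(dot_breaks) <= 0)) {
    stop("dot-product bin edges must be strictly ascending")
  }
  if (any(dot_breaks < 0 | dot_breaks > 1)) stop("dot-product edges must lie in [0,1]")
  if (!all(dim(scores) == c(length(distance_breaks) - 1L, length(dot_breaks) - 1L))) {
    stop("score grid shape does not match bin edges")
  }
  if (any(!is.finite(scores))) stop("non-finite score in grid")
  structure(list(distance_breaks = distance_breaks, dot_breaks = dot_breaks,
                 scores = scores),
            class = "scoring_matrix")
}

#' Read a scoring matrix from TSV
#'
#' Layout: line 1 = distance bin edges, line 2 = dot-product bin edges,
#' then the score grid row-major (one line per distance bin).
#'
#' @param file path or connection.
#' @return a [scoring_matrix()].
#' @export
read_scoring_matrix <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) < 3L) stop("scoring-matrix TSV needs 2 edge lines + grid")
  parse_row <- function(ln) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\t| +")[[1]]))
    if (anyNA(v)) stop("non-numeric value in scoring matrix")
    v
  }
  db <- parse_row(lines[1])
  ab <- parse_row(lines[2])
  grid <- do.call(rbind, lapply(lines[-(1:2)], parse_row))
  scoring_matrix(db, ab, grid)
}

#' Write a scoring matrix as TSV
#' @param sm a [scoring_matrix()].
#' @param file path; if `NULL` lines are returned.
#' @return invisibly, the lines written.
#' @export
write_scoring_matrix <- function(sm, file = NULL) {
  fmt <- function(v) paste(sprintf("%.17g", v), collapse = "\t")
  out <- c(fmt(sm$distance_breaks), fmt(sm$dot_breaks),
           apply(sm$scores, 1L, fmt))
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
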