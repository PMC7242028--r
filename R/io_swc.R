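# SWC skeleton format: one node per line, seven whitespace-separated
# columns (id, structure label, x, y, z, radius, parent id), '#' comments.

#' Read an SWC skeleton file
#'
#' @param file path or connection; lines starting with `#` and blank lines
#'   are ignored.
#' @param unit length-unit label to attach (default from [skt_options()]).
#' @param on_missing_parent passed to [build_neuron()]: `"error"` (default)
#'   rejects a parent id that references no node; `"root"` promotes the
#'   node to a root with a warning.
#' @return a [neuron][build_neuron]. A radius of 0 on disk is read back as
#'   missing when the neuron was written by [write_swc()] with missing
#'   radii (flagged in `meta$zero_radius_missing`).
#' @export
read_swc <- function(file, unit = NULL, on_missing_parent = c("error", "root")) {
  lines <- readLines(file, warn = FALSE)
  header <- lines[startsWith(trimws(lines), "#")]
  dat <- trimws(lines)
  dat <- dat[nzchar(dat) & !startsWith(dat, "#")]
  if (length(dat) == 0L) stop("no nodes: SWC file contains no data lines")
  fields <- strsplit(dat, "\\s+")
  if (any(lengths(fields) != 7L)) {
    stop("malformed SWC line (expected 7 columns): ",
         dat[which(lengths(fields) != 7L)[1]])
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7L, byrow = TRUE)
  if (any(!is.finite(m))) stop("non-numeric field in SWC data")
  nodes <- data.frame(id = as.integer(m[, 1]), label = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5],
                      radius = m[, 6], parent_id = as.integer(m[, 7]))
  unit_line <- grep("^#\\s*unit:", header, value = TRUE)
  if (is.null(unit) && length(unit_line)) {
    unit <- trimws(sub("^#\\s*unit:", "", unit_line[1]))
  }
  meta <- list(source_file = if (is.character(file)) file else NA_character_)
  if (any(grepl("missing radii written as 0", header))) {
    nodes$radius[nodes$radius == 0] <- NA_real_
    meta$zero_radius_missing <- TRUE
  }
  soma <- nodes$id[nodes$label == 1L & nodes$parent_id == -1L]
  soma <- if (length(soma) == 1L) soma else NULL
  build_neuron(nodes, soma_id = soma, unit = unit, meta = meta,
               on_missing_parent = match.arg(on_missing_parent))
}

#' Write a neuron as SWC
#'
#' Canonical 7-column whitespace format with a header comment recording
#' the unit. Missing radii are serialised as 0 (SWC has no null) and the
#' convention is flagged in the header so [read_swc()] restores them.
#'
#' @param neuron a [neuron][build_neuron].
#' @param file path or connection; if `NULL` the text is returned.
#' @return invisibly, the character vector of lines written.
#' @export
write_swc <- function(neuron, file = NULL) {
  d <- neuron$nodes
  radius <- d$radius
  header <- c("# SWC skeleton written by skeletoolkit",
              paste0("# unit: ", neuron$unit),
              "# columns: id label x y z radius parent_id")
  if (anyNA(radius)) {
    header <- c(header, "# missing radii written as 0")
    radius[is.na(radius)] <- 0
  }
  label <- d$label
  if (!is.null(neuron$soma_id)) label[d$id == neuron$soma_id] <- 1L
  body <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                  d$id, label, d$x, d$y, d$z, radius, d$parent_id)
  out <- c(header, body)
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
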