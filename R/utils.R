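# Internal helpers: logging, options, small vector geometry.

`%||%` <- function(a, b) if (is.null(a)) b else a

.skt_log_levels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

#' Set or query package options
#'
#' Package-wide defaults: `unit` (length-unit label attached to new
#' neurons), `strict` (collection mapping aborts on first error),
#' `log_level` (one of `"debug"`, `"info"`, `"warn"`, `"error"`).
#'
#' @param ... named options to set; with no arguments the current option
#'   list is returned.
#' @return invisibly, the previous values of the touched options.
#' @export
skt_options <- function(...) {
  new <- list(...)
  cur <- list(
    unit      = getOption("skeletoolkit.unit", "um"),
    strict    = getOption("skeletoolkit.strict", TRUE),
    log_level = getOption("skeletoolkit.log_level", "warn")
  )
  if (length(new) == 0L) return(cur)
  stopifnot(!is.null(names(new)), all(names(new) %in% names(cur)))
  old <- cur[names(new)]
  opts <- stats::setNames(new, paste0("skeletoolkit.", names(new)))
  do.call(options, opts)
  invisible(old)
}

#' Read a simple INI-style configuration file
#'
#' Lines of `key = value`; `#` or `;` start comments; section headers in
#' brackets are ignored. Recognised keys (`unit`, `strict`, `log_level`,
#' `seed`) are applied via [skt_options()] (`seed` via [set.seed()]).
#'
#' @param path file path.
#' @return the parsed key/value list, invisibly.
#' @export
skt_read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[#;].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    kv[[m[2]]] <- trimws(m[3])
  }
  if (!is.null(kv$unit)) skt_options(unit = kv$unit)
  if (!is.null(kv$strict)) skt_options(strict = tolower(kv$strict) %in% c("true", "1", "yes"))
  if (!is.null(kv$log_level)) skt_options(log_level = kv$log_level)
  if (!is.null(kv$seed)) set.seed(as.integer(kv$seed))
  invisible(kv)
}

skt_log <- function(level, ...) {
  lv <- .skt_log_levels[[level]]
  cur <- .skt_log_levels[[getOption("skeletoolkit.log_level", "warn")]]
  if (lv >= cur) {
    message(sprintf("[skeletoolkit %s] %s", level, paste0(..., collapse = "")))
  }
  invisible(NULL)
}

# Evaluate `expr` with a temporary RNG state seeded by `seed`; the caller's
# global RNG state is untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# row-wise cross product of n x 3 matrices (or a single 3-vector recycled)
cross3 <- function(a, b) {
  a <- matrix(a, ncol = 3L)
  b <- matrix(b, ncol = 3L)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norms <- function(m) sqrt(rowSums(m * m))

as_points3 <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) != 3L) stop("expected 3-column coordinates")
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-finite coordinates")
  dimnames(m) <- NULL
  m
}

check_same_unit <- function(ua, ub) {
  if (!identical(ua, ub)) {
    stop(sprintf("unit mismatch: '%s' vs '%s' (no implicit conversion)", ua, ub))
  }
  invisible(TRUE)
}
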