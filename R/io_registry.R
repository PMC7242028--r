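# Bridging-registry JSON and transform-file serialisation.
#
# Registry layout:
#   {"spaces": [{"name":..., "unit":..., "bbox_lo":[..], "bbox_hi":[..]}],
#    "bridges": [{"from":..., "to":..., "type":"affine"|"tps"|"flip+tps",
#                 "file":..., "invertible": true}]}
# Each bridge's "file" is a transform JSON (written by
# write_transform_json), resolved relative to the registry file.

#' Write a transform to JSON
#'
#' Serialises affine matrices, TPS control points/weights/affine parts,
#' flips and sequences; numeric inverses are stored as the wrapped
#' transform plus an `inverted` flag.
#'
#' @param t a `transform`.
#' @param file path; if `NULL` the JSON string is returned.
#' @return invisibly, the JSON string.
#' @export
write_transform_json <- function(t, file = NULL) {
  ser <- function(t) {
    switch(t$kind,
           affine = list(kind = "affine", matrix = as.vector(t$matrix)),
           flip = list(kind = "flip", axis = c("x", "y", "z")[t$axis],
                       lo = t$lo, hi = t$hi),
           tps = list(kind = "tps",
                      control = lapply(seq_len(nrow(t$control)),
                                       function(i) t$control[i, ]),
                      weights = lapply(seq_len(nrow(t$weights)),
                                       function(i) t$weights[i, ]),
                      affine = lapply(1:4, function(i) t$affine[i, ]),
                      lambda = t$lambda),
           sequence = list(kind = "sequence",
                           transforms = lapply(t$transforms, ser)),
           numeric_inverse = list(kind = "numeric_inverse",
                                  wrapped = ser(t$wrapped),
                                  tolerance = t$tolerance,
                                  max_iter = t$max_iter),
           stop("cannot serialise transform kind: ", t$kind))
  }
  txt <- jsonlite::toJSON(ser(t), auto_unbox = TRUE, digits = NA)
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

#' Read a transform from JSON
#' @param file path, connection or JSON string.
#' @return a `transform`.
#' @export
read_transform_json <- function(file) {
  de <- function(o) {
    switch(o$kind,
           affine = affine_transform(unlist(o$matrix)),
           flip = flip_transform(o$axis, o$lo, o$hi),
           tps = new_transform("tps", list(
             control = do.call(rbind, lapply(o$control, unlist)),
             weights = do.call(rbind, lapply(o$weights, unlist)),
             affine = do.call(rbind, lapply(o$affine, unlist)),
             lambda = o$lambda %||% 0)),
           sequence = sequence_transform(lapply(o$transforms, de)),
           numeric_inverse = new_transform("numeric_inverse", list(
             wrapped = de(o$wrapped),
             tolerance = o$tolerance %||% 1e-6,
             max_iter = as.integer(o$max_iter %||% 100L))),
           stop("unknown transform kind in JSON: ", o$kind))
  }
  de(jsonlite::fromJSON(file, simplifyVector = FALSE))
}

#' Read a bridging registry from JSON
#'
#' @param file registry JSON path; bridge transform files are resolved
#'   relative to its directory.
#' @return a [bridging_registry()].
#' @export
read_registry_json <- function(file) {
  doc <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  base_dir <- if (is.character(file) && file.exists(file)) dirname(file) else "."
  spaces <- lapply(doc$spaces, function(s) {
    template_space(name = s$name, unit = s$unit %||% NULL,
                   bbox_lo = unlist(s$bbox_lo), bbox_hi = unlist(s$bbox_hi),
                   mirror_axis = s$mirror_axis %||% "x")
  })
  bridges <- lapply(doc$bridges, function(b) {
    path <- b$file
    if (!file.exists(path)) path <- file.path(base_dir, b$file)
    list(from = b$from, to = b$to,
         transform = read_transform_json(path),
         invertible = isTRUE(b$invertible %||% TRUE))
  })
  bridging_registry(spaces, bridges)
}

#' Write a bridging registry to JSON
#'
#' Transform files are written next to the registry as
#' `<from>_to_<to>.transform.json`.
#'
#' @param registry a [bridging_registry()].
#' @param file registry JSON path.
#' @return invisibly, the registry path.
#' @export
write_registry_json <- function(registry, file) {
  dir <- dirname(file)
  bridges <- lapply(registry$bridges, function(b) {
    fn <- sprintf("%s_to_%s.transform.json", b$from, b$to)
    write_transform_json(b$transform, file.path(dir, fn))
    list(from = b$from, to = b$to,
         type = b$transform$kind, file = fn, invertible = b$invertible)
  })
  spaces <- lapply(registry$spaces, function(s) {
    list(name = s$name, unit = s$unit, bbox_lo = s$bbox_lo, bbox_hi = s$bbox_hi,
         mirror_axis = s$mirror_axis)
  })
  txt <- jsonlite::toJSON(list(spaces = unname(spaces), bridges = bridges),
                          auto_unbox = TRUE, digits = NA)
  writeLines(txt, file)
  invisible(file)
}
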