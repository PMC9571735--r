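#' Serialize and restore fast-and-frugal trees
#'
#' Trees are written as a small YAML (or JSON) document listing the ordered
#' nodes (`cue`, `direction`, `threshold`, `exit`) together with the
#' construction algorithm, goal weight and training balanced accuracy.
#' Round-trips are byte-stable: writing an unmodified re-read tree
#' reproduces the file exactly.
#'
#' @param tree An [fftree()].
#' @param path Output path; a `.json` extension selects JSON, anything else
#'   YAML.
#' @return `write_fftree()` returns `tree` invisibly; `read_fftree()`
#'   returns the restored [fftree()].
#' @export
write_fftree <- function(tree, path) {
  stopifnot(inherits(tree, "fftree"))
  doc <- list(
    algorithm = tree$algorithm,
    weight = tree$weight,
    goal_value = tree$goal_value,
    nodes = purrr::pmap(tree$nodes, function(cue, direction, threshold, exit) {
      list(cue = cue, direction = direction, threshold = threshold, exit = exit)
    })
  )
  doc <- purrr::discard(doc, function(x) length(x) == 1 && is.na(x))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path, precision = 15)
  }
  invisible(tree)
}

#' @rdname write_fftree
#' @export
read_fftree <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  nodes <- purrr::map_dfr(doc$nodes, function(n) {
    tibble::tibble(cue = n$cue, direction = n$direction,
                   threshold = as.numeric(n$threshold), exit = n$exit)
  })
  fftree(nodes,
         weight = if (is.null(doc$weight)) 0.5 else doc$weight,
         algorithm = if (is.null(doc$algorithm)) NA_character_ else doc$algorithm,
         goal_value = if (is.null(doc$goal_value)) NA_real_ else doc$goal_value)
}
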