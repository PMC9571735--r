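#' The published pre-operative screening tree
#'
#' The pre-operative fast-and-frugal tree proposed for POD risk screening
#' uses four cues in fixed order: Charlson Comorbidity Index, site of
#' surgery, ASA physical status and frailty status. The first node is
#' anchored by its published description (CCI greater than 1 exits
#' positive); the exits and thresholds of the middle nodes are defaults
#' inferred from the cohort's class-conditional marginals (peripheral
#' surgery is far more common without POD, ASA 3--4 with POD) and can be
#' overridden.
#'
#' Default structure:
#' 1. `cci > 1` -> positive exit
#' 2. `surgery_site > 2` (peripheral) -> negative exit
#' 3. `asa_ps > 2` -> positive exit
#' 4. `frailty > 0` (pre-frail/frail) -> positive, `<= 0` (robust) ->
#'    negative (final node).
#'
#' @param thresholds Named numeric overrides per cue (e.g.
#'   `c(asa_ps = 3)`).
#' @param exits Named character overrides (`"positive"`/`"negative"`) for
#'   the non-final nodes.
#' @return An [fftree()].
#' @examples
#' screen(data.frame(cci = 3, surgery_site = 2, asa_ps = 2, frailty = 1),
#'        preoperative_tree())
#' @export
preoperative_tree <- function(thresholds = NULL, exits = NULL) {
  nodes <- tibble::tibble(
    cue = c("cci", "surgery_site", "asa_ps", "frailty"),
    direction = c(">", ">", ">", ">"),
    threshold = c(1, 2, 2, 0),
    exit = c("positive", "negative", "positive", "both")
  )
  frozen_tree(nodes, thresholds, exits, algorithm = "frozen-preoperative")
}

#' The published postoperative screening tree
#'
#' The postoperative tree uses three cues in fixed order: duration of
#' anesthesia, age and CCI. Its numeric cut points were published only
#' graphically and are not printed in the text, so this constructor ships
#' no default thresholds: all three must be supplied. Non-final exits
#' default to positive on the high side of each cue and can be overridden.
#'
#' @param thresholds Named numeric vector with entries
#'   `anesthesia_duration`, `age` and `cci` (required).
#' @param exits Named character overrides for the non-final nodes.
#' @return An [fftree()] of depth 3 (final node carries both exits).
#' @examples
#' postoperative_tree(c(anesthesia_duration = 300, age = 73, cci = 2))
#' @export
postoperative_tree <- function(thresholds, exits = NULL) {
  cues <- c("anesthesia_duration", "age", "cci")
  if (missing(thresholds) || !all(cues %in% names(thresholds))) {
    stop("thresholds for ", paste(cues, collapse = ", "), " are required: ",
         "the published figure's cut points are not printed in the text ",
         "and no defaults are assumed", call. = FALSE)
  }
  nodes <- tibble::tibble(
    cue = cues,
    direction = c(">", ">", ">"),
    threshold = as.numeric(thresholds[cues]),
    exit = c("positive", "positive", "both")
  )
  frozen_tree(nodes, NULL, exits, algorithm = "frozen-postoperative")
}

frozen_tree <- function(nodes, thresholds, exits, algorithm) {
  for (ov in names(thresholds)) {
    if (!ov %in% nodes$cue) {
      stop("threshold override for foreign cue '", ov, "'", call. = FALSE)
    }
    nodes$threshold[nodes$cue == ov] <- thresholds[[ov]]
  }
  for (ov in names(exits)) {
    i <- match(ov, nodes$cue)
    if (is.na(i)) stop("exit override for foreign cue '", ov, "'", call. = FALSE)
    if (i == nrow(nodes)) {
      stop("the final node always carries both exits", call. = FALSE)
    }
    if (!exits[[ov]] %in% c("positive", "negative")) {
      stop("exit must be 'positive' or 'negative'", call. = FALSE)
    }
    if (exits[[ov]] != nodes$exit[i]) {
      nodes$direction[i] <- flip_direction(nodes$direction[i])
      nodes$exit[i] <- exits[[ov]]
    }
  }
  fftree(nodes, algorithm = algorithm)
}

#' Screen a cohort with a decision tree
#'
#' Applies a (typically frozen) fast-and-frugal tree to a cohort and
#' returns the per-patient flagged/not-flagged report; when the outcome
#' column is present the classification performance is attached.
#'
#' @param data Imputed cohort tibble containing the tree's cues.
#' @param tree An [fftree()].
#' @param outcome Outcome column name; performance is computed only when
#'   this column exists.
#' @return A `pod_screen` object: `$decisions` (tibble with `patient`,
#'   `decision`, `flagged`, `cues_used`), `$stats` (a [perf_stats()] row or
#'   `NULL`) and `$tree`.
#' @export
screen <- function(data, tree, outcome = "pod") {
  stopifnot(inherits(tree, "fftree"))
  absent <- setdiff(tree$nodes$cue, names(data))
  if (length(absent) > 0) {
    stop("cue column(s) missing from cohort: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0) {
    decisions <- tibble::tibble(patient = integer(0), decision = integer(0),
                                flagged = logical(0), cues_used = integer(0))
    return(structure(list(decisions = decisions, stats = NULL, tree = tree),
                     class = "pod_screen"))
  }
  res <- classify(data, tree)
  decisions <- tibble::tibble(
    patient = seq_len(nrow(data)),
    decision = res$decision,
    flagged = res$decision == 1L,
    cues_used = res$cues_used
  )
  stats <- if (outcome %in% names(data)) evaluate(data, tree, outcome = outcome)
  structure(list(decisions = decisions, stats = stats, tree = tree),
            class = "pod_screen")
}

#' @export
print.pod_screen <- function(x, ...) {
  n <- nrow(x$decisions)
  cat("<pod_screen>", n, "patients |", sum(x$decisions$flagged),
      "flagged for intensified POD screening\n")
  if (!is.null(x$stats)) {
    cat(sprintf("  sens %.3f | spec %.3f | bacc %.3f | acc %.3f | mcu %.2f\n",
                x$stats$sens, x$stats$spec, x$stats$bacc, x$stats$acc,
                x$stats$mcu))
  }
  invisible(x)
}

#' @export
tidy.pod_screen <- function(x, ...) x$decisions

#' @export
glance.pod_screen <- function(x, ...) {
  base <- tibble::tibble(
    n = nrow(x$decisions),
    flagged = sum(x$decisions$flagged),
    flagged_rate = mean(x$decisions$flagged)
  )
  if (is.null(x$stats)) base else dplyr::bind_cols(base, x$stats)
}
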