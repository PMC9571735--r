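#' Read a patient cohort from CSV
#'
#' Reads a patient-level table with one row per patient, one column per cue
#' and a binary outcome column (1 = postoperative delirium). Empty cells and
#' `"."` are treated as missing; cells that cannot be parsed under the cue's
#' declared kind also become missing. Columns not present in the cue
#' dictionary are dropped with a warning.
#'
#' @param path Path to a CSV file with a header row.
#' @param cue_dict Cue dictionary, as returned by [pod_cues()].
#' @param outcome Name of the outcome column. Must be present and strictly
#'   binary (0/1); otherwise an error is raised.
#' @return A tibble with the outcome column and the dictionary cues that
#'   occur in the file, cue values numeric with `NA` as the missing marker.
#' @seealso [write_cohort()], [impute_missing()]
#' @examples
#' path <- system.file("extdata", "synthetic_cohort_30.csv", package = "frugalpod")
#' cohort <- read_cohort(path)
#' impute_missing(cohort)
#' @export
read_cohort <- function(path, cue_dict = pod_cues(), outcome = "pod") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "."), progress = FALSE)
  if (!outcome %in% names(raw)) {
    stop("outcome column '", outcome, "' missing from ", path, call. = FALSE)
  }
  unknown <- setdiff(names(raw), c(outcome, cue_dict$cue))
  if (length(unknown) > 0) {
    warning("dropping unknown column(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
    raw <- raw[setdiff(names(raw), unknown)]
  }
  parsed <- dplyr::mutate(raw, dplyr::across(
    dplyr::everything(),
    function(x) suppressWarnings(as.numeric(x))
  ))
  check_outcome(parsed, outcome)
  parsed[[outcome]] <- as.integer(parsed[[outcome]])
  # stable column order: outcome last, cues in dictionary order
  cues <- intersect(cue_dict$cue, names(parsed))
  parsed[c(cues, outcome)]
}

#' Write a patient cohort to CSV
#'
#' Missing cue values are written as empty cells, the convention
#' [read_cohort()] reads back.
#'
#' @param data Cohort tibble.
#' @param path Output CSV path.
#' @return `data`, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(data)
}

#' Replace missing cue values
#'
#' Applies the study's deterministic single-imputation rules, computed on the
#' full table (before any train/test splitting): ISCED, GDS, pack years and
#' duration of anesthesia get the sample median of the observed values; the
#' named comorbidities (arterial hypertension, coronary artery disease,
#' diabetes, stroke/TIA), pre-operative cognitive impairment, ADL, IADL and
#' premedication get the constant 0 (no impairment); MNA gets the constant 3
#' (no impairment). Any other cue falls back to its dictionary rule: median
#' for numeric cues, mode for ordinal/binary cues.
#'
#' Medians of ordinal or integer-coded cues are rounded half-up onto the
#' cue's coding grid; mode ties resolve to the smallest value. Observed
#' values, the outcome column and the row count are never altered, so the
#' operation is idempotent.
#'
#' @inheritParams read_cohort
#' @param data Cohort tibble (may contain `NA` cue values).
#' @return The cohort with no missing cue values.
#' @export
impute_missing <- function(data, cue_dict = pod_cues(), outcome = "pod") {
  if (nrow(data) == 0) stop("cannot impute an empty table", call. = FALSE)
  check_outcome(data, outcome)
  for (cue in intersect(cue_dict$cue, names(data))) {
    x <- data[[cue]]
    if (!anyNA(x)) next
    spec <- cue_dict[cue_dict$cue == cue, ]
    fill <- switch(spec$impute,
      constant = spec$impute_value,
      median = grid_median(x[!is.na(x)], spec, cue),
      mode = smallest_mode(x[!is.na(x)], cue)
    )
    x[is.na(x)] <- fill
    data[[cue]] <- x
  }
  data
}

# median with half-up rounding back onto the coding grid for ordinal /
# integer-coded cues; even-count samples use the mean of the two central
# order statistics (stats::median, type-7 on numerics)
grid_median <- function(x, spec, cue) {
  if (length(x) == 0) {
    stop("cue '", cue, "' is entirely missing; median imputation impossible",
         call. = FALSE)
  }
  m <- stats::median(x)
  if (!is.null(spec$levels[[1]])) {
    lv <- sort(spec$levels[[1]])
    # nearest legal level, half-up on ties
    below <- max(c(lv[lv <= m], -Inf))
    above <- min(c(lv[lv >= m], Inf))
    m <- if (m - below < above - m) below else above
    if (!is.finite(m)) m <- if (is.finite(below)) below else above
  } else if (isTRUE(spec$integer_coded)) {
    m <- floor(m + 0.5)
  }
  m
}

# most frequent value; ties resolve to the smallest value
smallest_mode <- function(x, cue) {
  if (length(x) == 0) {
    stop("cue '", cue, "' is entirely missing; mode imputation impossible",
         call. = FALSE)
  }
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)][1])  # table() orders names ascending
}

#' Split a cohort into equal halves
#'
#' Uniform random partition without replacement into a training half of
#' `ceiling(n / 2)` rows and a test half of `floor(n / 2)` rows, the split
#' geometry of the repeated paired-split model comparison (394 patients give
#' two halves of 197). Deterministic given `seed`.
#'
#' @param data Cohort tibble with at least 2 rows.
#' @param seed Integer seed controlling the partition.
#' @return An object of class `split_pair`: a list with tibbles `train` and
#'   `test`, the `seed`, and the row indices of the training half.
#' @export
split_half <- function(data, seed) {
  n <- nrow(data)
  if (n < 2) stop("need at least 2 rows to split", call. = FALSE)
  idx <- withr::with_seed(seed, sample.int(n, ceiling(n / 2)))
  idx <- sort(idx)
  structure(
    list(train = data[idx, , drop = FALSE],
         test = data[-idx, , drop = FALSE],
         train_idx = idx,
         seed = as.integer(seed)),
    class = "split_pair"
  )
}

#' @export
print.split_pair <- function(x, ...) {
  cat("<split_pair> train n =", nrow(x$train),
      "| test n =", nrow(x$test), "| seed =", x$seed, "\n")
  invisible(x)
}

# counter-based per-trial seed derivation: reproducible in isolation,
# stays below 2^31
derive_seed <- function(master_seed, counter) {
  as.integer((as.double(master_seed) * 48271 + counter * 7919) %% 2147483629)
}
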