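#' The four default model specifications
#'
#' The model set of the repeated-split comparison: fast-and-frugal trees
#' built with ifan (max depth 5) and dfan (max depth 4), the
#' misclassification-weighted recursive-partitioning tree (UDT), and the
#' base-rate-thresholded logistic regression. dfan is flagged `slow`, so
#' [run_comparison()] restricts it to the first `n_trials_slow` splits.
#'
#' A model specification is a list with elements `fit(train, cues)` and
#' `predict(model, data)` (returning 0/1 decisions), an `evaluate(data,
#' model)` override (optional; defaults to decision-based confusion counts)
#' and a `slow` flag.
#'
#' @return Named list of model specifications
#'   (`FFTi`, `FFTd`, `UDT`, `LogReg`).
#' @export
pod_models <- function() {
  list(
    FFTi = list(
      fit = function(train, cues) build_ifan(train, max_levels = 5, cues = cues),
      evaluate = function(data, model) evaluate(data, model),
      slow = FALSE
    ),
    FFTd = list(
      fit = function(train, cues) build_dfan(train, max_levels = 4, cues = cues),
      evaluate = function(data, model) evaluate(data, model),
      slow = TRUE
    ),
    UDT = list(
      fit = function(train, cues) fit_weighted_tree(train, cues = cues),
      evaluate = function(data, model) evaluate(data, model),
      slow = FALSE
    ),
    LogReg = list(
      fit = function(train, cues) suppressWarnings(fit_threshold_logreg(train, cues = cues)),
      evaluate = function(data, model) evaluate(data, model),
      slow = FALSE
    )
  )
}

#' Run the repeated paired-split model comparison
#'
#' The dataset is repeatedly split at random into equal train and test
#' halves; within each trial every model is fitted on the identical training
#' half and evaluated on both halves, so performance differences are
#' within-split (paired). Slow-flagged models run only on the first
#' `n_trials_slow` splits. Per-trial split seeds derive from `seed` by a
#' fixed counter formula, making each trial reproducible in isolation and
#' the "first k splits" well defined across machines.
#'
#' Individual model failures (e.g. a degenerate training half) are recorded
#' and skipped; a model failing on more than 1% of its trials aborts the run
#' with diagnostics.
#'
#' @param data Imputed cohort tibble (no missing cue values).
#' @param models Named list of model specifications, see [pod_models()].
#' @param cues Cue columns handed to every model; default all non-outcome
#'   columns.
#' @param n_trials Number of paired splits for fast models (study protocol:
#'   10000).
#' @param n_trials_slow Number of initial splits slow models run on (study
#'   protocol: 1000). Must not exceed `n_trials`.
#' @param seed Master seed.
#' @param outcome Outcome column name.
#' @return A `pod_comparison` object: per-trial tidy metrics in `$trials`
#'   (columns `trial`, `seed`, `model`, `phase`, confusion counts and
#'   metrics), plus the run settings.
#' @export
run_comparison <- function(data, models = pod_models(), cues = NULL,
                           n_trials = 10000, n_trials_slow = 1000,
                           seed = 1, outcome = "pod") {
  stopifnot(n_trials >= 1, n_trials_slow <= n_trials)
  check_outcome(data, outcome)
  if (is.null(cues)) cues <- cue_columns(data, outcome)
  if (anyNA(data[cues])) {
    stop("cohort contains missing cue values; run impute_missing() first",
         call. = FALSE)
  }
  rows <- vector("list", n_trials * length(models))
  failures <- stats::setNames(integer(length(models)), names(models))
  k <- 0L
  for (t in seq_len(n_trials)) {
    trial_seed <- derive_seed(seed, t)
    pair <- split_half(data, trial_seed)
    for (m in names(models)) {
      spec <- models[[m]]
      if (isTRUE(spec$slow) && t > n_trials_slow) next
      res <- tryCatch({
        fit <- spec$fit(pair$train, cues)
        dplyr::bind_rows(
          dplyr::mutate(spec$evaluate(pair$train, fit), phase = "train"),
          dplyr::mutate(spec$evaluate(pair$test, fit), phase = "test")
        )
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) {
        failures[m] <- failures[m] + 1L
        rows[[k <- k + 1L]] <- tibble::tibble(
          trial = t, seed = trial_seed, model = m, phase = "failed",
          error = res
        )
      } else {
        rows[[k <- k + 1L]] <- dplyr::mutate(
          res, trial = t, seed = trial_seed, model = m, error = NA_character_
        )
      }
    }
    ran <- vapply(models, function(s) if (isTRUE(s$slow)) min(t, n_trials_slow) else t, 0)
    bad <- failures / pmax(ran, 1) > 0.01 & failures > 1
    if (any(bad)) {
      stop("model(s) failing on > 1% of trials: ",
           paste(names(models)[bad], " (", failures[bad], " failures)",
                 sep = "", collapse = ", "), call. = FALSE)
    }
  }
  trials <- dplyr::relocate(dplyr::bind_rows(rows[seq_len(k)]),
                            "trial", "seed", "model", "phase")
  structure(
    list(trials = trials, models = names(models),
         n_trials = n_trials, n_trials_slow = n_trials_slow,
         seed = seed, failures = failures),
    class = "pod_comparison"
  )
}

#' @export
print.pod_comparison <- function(x, ...) {
  cat("<pod_comparison>", x$n_trials, "paired splits (slow models:",
      x$n_trials_slow, ") | models:", paste(x$models, collapse = ", "), "\n")
  print(aggregate_comparison(x))
  invisible(x)
}

#' @export
tidy.pod_comparison <- function(x, ...) x$trials

#' Aggregate a model comparison
#'
#' Per-model, per-phase means and standard errors of sensitivity,
#' specificity and balanced accuracy across trials (SE = sample SD /
#' sqrt(number of successful trials)), the layout of the study's performance
#' tables.
#'
#' @param x A `pod_comparison`.
#' @return A tibble with one row per model and phase.
#' @export
aggregate_comparison <- function(x) {
  stopifnot(inherits(x, "pod_comparison"))
  se <- function(v) stats::sd(v) / sqrt(length(v))
  x$trials |>
    dplyr::filter(.data$phase != "failed") |>
    dplyr::group_by(.data$model, .data$phase) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      dplyr::across(c("sens", "spec", "bacc"),
                    list(mean = mean, se = se)),
      .groups = "drop"
    ) |>
    dplyr::arrange(factor(.data$model, levels = x$models),
                   dplyr::desc(.data$phase))
}

#' @export
glance.pod_comparison <- function(x, ...) {
  agg <- aggregate_comparison(x)
  test <- agg[agg$phase == "test", ]
  tibble::tibble(
    n_trials = x$n_trials, n_trials_slow = x$n_trials_slow,
    n_models = length(x$models),
    best_test_model = test$model[which.max(test$bacc_mean)],
    best_test_bacc = max(test$bacc_mean),
    failures = sum(x$failures)
  )
}

#' Pairwise win rate between two models
#'
#' Fraction of common trials (trials where both models ran successfully) in
#' which model `a`'s test balanced accuracy strictly exceeds model `b`'s.
#' Exact ties are credited to neither model, so `win_rate(x, a, b) +
#' win_rate(x, b, a)` can fall below 1.
#'
#' @param x A `pod_comparison`.
#' @param a,b Model names.
#' @return A fraction in `[0, 1]`.
#' @export
win_rate <- function(x, a, b) {
  stopifnot(inherits(x, "pod_comparison"))
  test <- x$trials[x$trials$phase == "test", c("trial", "model", "bacc")]
  wide <- tidyr::pivot_wider(test, names_from = "model", values_from = "bacc")
  if (!all(c(a, b) %in% names(wide))) {
    stop("unknown model name(s): ",
         paste(setdiff(c(a, b), names(wide)), collapse = ", "), call. = FALSE)
  }
  common <- !is.na(wide[[a]]) & !is.na(wide[[b]])
  if (!any(common)) stop("models share no common trials", call. = FALSE)
  mean(wide[[a]][common] > wide[[b]][common])
}

#' Pairwise win-rate matrix
#'
#' @param x A `pod_comparison`.
#' @return A square matrix; entry `[a, b]` is [win_rate()] of `a` over `b`
#'   (diagonal 0).
#' @export
win_matrix <- function(x) {
  stopifnot(inherits(x, "pod_comparison"))
  m <- matrix(0, length(x$models), length(x$models),
              dimnames = list(x$models, x$models))
  for (a in x$models) for (b in setdiff(x$models, a)) {
    m[a, b] <- win_rate(x, a, b)
  }
  m
}
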