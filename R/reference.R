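#' Parameters of the misclassification-weighted recursive-partitioning tree
#'
#' The unconstrained comparator tree (UDT) is a CART-style classifier grown
#' with a minimum node size of 20 and a cost-complexity parameter of
#' 0.00001, with misclassified positive cases weighted by the ratio of
#' negative to positive cases in the training set so that the tree targets
#' balanced accuracy despite the class imbalance.
#'
#' @param min_split Minimum number of cases in a node before a split is
#'   attempted (default 20).
#' @param complexity Cost-complexity pruning parameter (default 1e-5).
#' @return A `weighted_tree_params` list.
#' @export
weighted_tree_params <- function(min_split = 20, complexity = 0.00001) {
  stopifnot(min_split >= 2, complexity >= 0)
  structure(list(min_split = min_split, complexity = complexity),
            class = "weighted_tree_params")
}

#' Fit the misclassification-weighted comparator tree
#'
#' Grows a binary recursive-partitioning classifier (via [rpart::rpart()])
#' under case weights that up-weight positive cases by the training ratio of
#' negatives to positives, with the stated minimum split size and
#' cost-complexity parameter.
#'
#' @param data Training cohort (no missing cue values, both classes
#'   present).
#' @param cues Cue columns to use; default all non-outcome columns.
#' @param params A [weighted_tree_params()].
#' @param outcome Outcome column name.
#' @return An object of class `pod_udt` wrapping the rpart fit; its
#'   `positive_weight` element is the applied negative/positive ratio.
#' @export
fit_weighted_tree <- function(data, cues = NULL, params = weighted_tree_params(),
                              outcome = "pod") {
  y <- check_outcome(data, outcome)
  if (is.null(cues)) cues <- cue_columns(data, outcome)
  npos <- sum(y == 1L)
  nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("both classes are required to fit the weighted tree", call. = FALSE)
  }
  positive_weight <- nneg / npos
  df <- as.data.frame(data[cues])
  df$.outcome <- factor(y, levels = c(0, 1))
  fit <- rpart::rpart(
    .outcome ~ ., data = df,
    weights = ifelse(y == 1L, positive_weight, 1),
    method = "class",
    control = rpart::rpart.control(minsplit = params$min_split,
                                   cp = params$complexity)
  )
  structure(list(fit = fit, cues = cues, params = params,
                 positive_weight = positive_weight),
            class = "pod_udt")
}

#' @export
print.pod_udt <- function(x, ...) {
  cat("<pod_udt> weighted recursive-partitioning tree |",
      "positive weight", format(x$positive_weight, digits = 4),
      "| minsplit", x$params$min_split, "| cp", x$params$complexity, "\n")
  invisible(x)
}

#' Fit the base-rate-thresholded logistic comparator
#'
#' Maximum-likelihood logistic regression (via [stats::glm()]) on the given
#' cues (ordinal cues enter as their numeric codes, binary cues as 0/1),
#' with the probability-to-decision threshold set to the positive base rate
#' of the training set: predicting positive whenever the estimated POD
#' probability is at least the training prevalence targets balanced
#' accuracy rather than raw accuracy. Perfect separation yields the usual
#' glm warning; predictions remain defined.
#'
#' @inheritParams fit_weighted_tree
#' @return An object of class `pod_logreg` with elements `fit`,
#'   `coefficients`, `threshold` and `cues`.
#' @export
fit_threshold_logreg <- function(data, cues = NULL, outcome = "pod") {
  y <- check_outcome(data, outcome)
  if (is.null(cues)) cues <- cue_columns(data, outcome)
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L) {
    stop("both classes are required to fit the logistic model", call. = FALSE)
  }
  df <- as.data.frame(data[cues])
  df$.outcome <- y
  fit <- stats::glm(.outcome ~ ., data = df, family = stats::binomial())
  structure(list(fit = fit, coefficients = stats::coef(fit),
                 threshold = mean(y), cues = cues),
            class = "pod_logreg")
}

#' @export
print.pod_logreg <- function(x, ...) {
  cat("<pod_logreg> logistic model on", length(x$cues), "cues |",
      "decision threshold (training base rate)",
      format(x$threshold, digits = 4), "\n")
  invisible(x)
}

#' @export
tidy.pod_logreg <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @export
glance.pod_logreg <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold, n = length(x$fit$y),
    deviance = x$fit$deviance, aic = x$fit$aic
  )
}

#' Predict POD decisions with a fitted comparator
#'
#' The weighted tree predicts each case's majority-weighted leaf class; the
#' logistic model predicts positive whenever the estimated probability is
#' greater than or equal to its base-rate threshold (ties at the threshold
#' count as positive).
#'
#' @param object A fitted `pod_udt` or `pod_logreg`.
#' @param data Cohort tibble containing the model's cues, no missing
#'   values.
#' @param ... Unused.
#' @return Integer vector of 0/1 decisions, one per row.
#' @name predict-comparators
NULL

#' @rdname predict-comparators
#' @export
predict.pod_udt <- function(object, data, ...) {
  if (nrow(data) == 0) return(integer(0))
  check_model_cues(object$cues, data)
  cls <- stats::predict(object$fit, newdata = as.data.frame(data[object$cues]),
                        type = "class")
  as.integer(as.character(cls))
}

#' @rdname predict-comparators
#' @export
predict.pod_logreg <- function(object, data, ...) {
  if (nrow(data) == 0) return(integer(0))
  check_model_cues(object$cues, data)
  p <- stats::predict(object$fit, newdata = as.data.frame(data[object$cues]),
                      type = "response")
  as.integer(p >= object$threshold)
}

check_model_cues <- function(cues, data) {
  absent <- setdiff(cues, names(data))
  if (length(absent) > 0) {
    stop("cue(s) missing from table: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(data[cues])) {
    stop("missing cue values; impute before predicting", call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname evaluate
#' @export
evaluate.pod_udt <- function(data, model, ..., outcome = "pod") {
  evaluate_decisions(data, stats::predict(model, data), outcome)
}

#' @rdname evaluate
#' @export
evaluate.pod_logreg <- function(data, model, ..., outcome = "pod") {
  evaluate_decisions(data, stats::predict(model, data), outcome)
}

evaluate_decisions <- function(data, decision, outcome) {
  if (nrow(data) == 0) stop("cannot evaluate on an empty table", call. = FALSE)
  y <- check_outcome(data, outcome)
  cc <- confusion(y, decision)
  perf_stats(cc$hi, cc$mi, cc$fa, cc$cr)
}

#' Serialize a comparator model to JSON
#'
#' Writes the reproducibility-relevant parts of a fitted model: the logistic
#' model's coefficients and threshold, or the weighted tree's split frame,
#' weight ratio and control parameters.
#'
#' @param model A `pod_udt` or `pod_logreg`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to `path`.
#' @export
model_to_json <- function(model, path = NULL) {
  doc <- if (inherits(model, "pod_logreg")) {
    list(model = "logreg", coefficients = as.list(model$coefficients),
         threshold = model$threshold, cues = model$cues)
  } else if (inherits(model, "pod_udt")) {
    frame <- model$fit$frame
    list(model = "udt", positive_weight = model$positive_weight,
         min_split = model$params$min_split,
         complexity = model$params$complexity,
         frame = data.frame(var = as.character(frame$var), n = frame$n,
                            yval = frame$yval))
  } else {
    stop("unsupported model class", call. = FALSE)
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
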