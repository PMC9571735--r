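#' Construct a fast-and-frugal tree by hand
#'
#' A fast-and-frugal tree (FFT) is an ordered list of single-cue threshold
#' rules. Every non-final node carries exactly one exit: cases satisfying the
#' rule leave immediately with the exit's decision (`"positive"` = at risk,
#' `"negative"` = not at risk) and all other cases descend to the next node.
#' The final node has both exits (`"both"`): its rule decides positive when
#' satisfied and negative otherwise.
#'
#' @param nodes A data frame with columns `cue` (name), `direction`
#'   (`">"` or `"<="`), `threshold` (numeric, on the cue's coding scale) and
#'   `exit` (`"positive"`, `"negative"` or `"both"`).
#' @param weight Sensitivity weight of the construction goal
#'   `weight * sens + (1 - weight) * spec`; `0.5` is balanced accuracy.
#' @param algorithm Optional label of the construction algorithm.
#' @param goal_value Balanced accuracy on the training set, if known.
#' @return An object of class `fftree`.
#' @examples
#' fftree(data.frame(
#'   cue = c("cci", "frailty"), direction = c(">", ">"),
#'   threshold = c(1, 0), exit = c("positive", "both")
#' ))
#' @export
fftree <- function(nodes, weight = 0.5, algorithm = NA_character_,
                   goal_value = NA_real_) {
  nodes <- tibble::as_tibble(nodes)
  required <- c("cue", "direction", "threshold", "exit")
  if (!all(required %in% names(nodes))) {
    stop("nodes need columns ", paste(required, collapse = ", "), call. = FALSE)
  }
  nodes <- nodes[required]
  d <- nrow(nodes)
  if (d < 1) stop("a tree needs at least one node", call. = FALSE)
  if (anyDuplicated(nodes$cue)) stop("no cue may appear twice", call. = FALSE)
  if (!all(nodes$direction %in% c(">", "<="))) {
    stop("direction must be '>' or '<='", call. = FALSE)
  }
  if (nodes$exit[d] != "both") stop("final node must have exit 'both'", call. = FALSE)
  if (d > 1 && !all(nodes$exit[-d] %in% c("positive", "negative"))) {
    stop("non-final nodes must exit 'positive' or 'negative'", call. = FALSE)
  }
  structure(
    list(nodes = nodes, weight = weight, algorithm = algorithm,
         goal_value = goal_value),
    class = "fftree"
  )
}

#' @export
print.fftree <- function(x, ...) {
  d <- nrow(x$nodes)
  cat("<fftree>", if (!is.na(x$algorithm)) paste0("[", x$algorithm, "]"),
      "depth", d,
      if (!is.na(x$goal_value)) sprintf("| training bacc %.3f", x$goal_value),
      "\n")
  for (i in seq_len(d)) {
    n <- x$nodes[i, ]
    rule <- sprintf("%s %s %g", n$cue, n$direction, n$threshold)
    if (n$exit == "both") {
      cat(sprintf("  %d. if %s: POSITIVE else NEGATIVE\n", i, rule))
    } else {
      cat(sprintf("  %d. if %s: %s else continue\n", i, rule, toupper(n$exit)))
    }
  }
  invisible(x)
}

#' @export
tidy.fftree <- function(x, ...) {
  dplyr::mutate(x$nodes, node = dplyr::row_number(), .before = 1)
}

#' @export
glance.fftree <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm, depth = nrow(x$nodes),
    cues = paste(x$nodes$cue, collapse = ";"),
    weight = x$weight, goal_value = x$goal_value
  )
}

# walk all rows through the tree; returns decision and exit depth vectors
fft_apply <- function(tree, data) {
  nodes <- tree$nodes
  n <- nrow(data)
  decision <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  remaining <- rep(TRUE, n)
  for (i in seq_len(nrow(nodes))) {
    cue <- nodes$cue[i]
    if (!cue %in% names(data)) {
      stop("cue '", cue, "' not present in the table", call. = FALSE)
    }
    v <- data[[cue]]
    if (anyNA(v[remaining])) {
      stop("missing value for cue '", cue, "'; impute before classifying",
           call. = FALSE)
    }
    cond <- if (nodes$direction[i] == ">") v > nodes$threshold[i] else v <= nodes$threshold[i]
    if (nodes$exit[i] == "both") {
      decision[remaining] <- as.integer(cond[remaining])
      depth[remaining] <- i
      remaining <- remaining & FALSE
    } else {
      out <- remaining & cond
      decision[out] <- if (nodes$exit[i] == "positive") 1L else 0L
      depth[out] <- i
      remaining <- remaining & !cond
    }
  }
  list(decision = decision, cues_used = depth)
}

#' Classify patients with a fast-and-frugal tree
#'
#' Walks every row through the tree's nodes in order, recording the decision
#' and the number of cue values looked up (equal to the exit depth).
#'
#' @param data Cohort tibble; must contain every tree cue with no missing
#'   values among the rows that reach the cue.
#' @param tree An [fftree()].
#' @return A tibble with columns `decision` (1 = flagged at risk),
#'   `cues_used` and `exit_depth`, one row per input row.
#' @export
classify <- function(data, tree) {
  stopifnot(inherits(tree, "fftree"))
  res <- fft_apply(tree, data)
  tibble::tibble(decision = res$decision, cues_used = res$cues_used,
                 exit_depth = res$cues_used)
}

#' Assemble classification performance statistics
#'
#' Builds the standard performance record from confusion counts: sensitivity
#' `hi / (hi + mi)`, specificity `cr / (cr + fa)`, balanced accuracy
#' `(sens + spec) / 2`, unweighted accuracy `(hi + cr) / n`, plus the
#' frugality measures mean cues used (`mcu`) and percent cues ignored
#' (`pci = 1 - mcu / n_cues`). Ratios whose denominator is zero (single-class
#' tables) are returned as `NaN`.
#'
#' @param hi,mi,fa,cr Hit, miss, false-alarm and correct-rejection counts.
#' @param mcu Mean number of cues looked up per case (`NA` for models
#'   without sequential lookup).
#' @param n_cues Number of cues available in the table, the denominator of
#'   `pci`.
#' @return A one-row tibble.
#' @examples
#' perf_stats(hi = 84, mi = 16, fa = 54, cr = 46)
#' @export
perf_stats <- function(hi, mi, fa, cr, mcu = NA_real_, n_cues = NA_integer_) {
  stopifnot(hi >= 0, mi >= 0, fa >= 0, cr >= 0)
  sens <- hi / (hi + mi)
  spec <- cr / (cr + fa)
  n <- hi + mi + fa + cr
  tibble::tibble(
    hi = as.integer(hi), mi = as.integer(mi),
    fa = as.integer(fa), cr = as.integer(cr),
    sens = sens, spec = spec, bacc = (sens + spec) / 2,
    acc = (hi + cr) / n, mcu = mcu,
    pci = 1 - mcu / n_cues
  )
}

# confusion counts of predicted decisions against the outcome
confusion <- function(truth, decision) {
  list(
    hi = sum(truth == 1L & decision == 1L),
    mi = sum(truth == 1L & decision == 0L),
    fa = sum(truth == 0L & decision == 1L),
    cr = sum(truth == 0L & decision == 0L)
  )
}

#' Evaluate a fitted model on a cohort
#'
#' Computes confusion counts and the derived metrics of [perf_stats()] for a
#' fast-and-frugal tree, a weighted recursive-partitioning tree or a
#' thresholded logistic model on a labelled cohort. For FFTs the frugality
#' measures are included; the `pci` denominator is the number of cue columns
#' present in `data`.
#'
#' @param data Labelled cohort tibble.
#' @param model A fitted model object.
#' @param outcome Name of the binary outcome column.
#' @param ... Passed to methods.
#' @return A one-row [perf_stats()] tibble.
#' @export
evaluate <- function(data, model, ..., outcome = "pod") {
  UseMethod("evaluate", model)
}

#' @rdname evaluate
#' @export
evaluate.fftree <- function(data, model, ..., outcome = "pod") {
  if (nrow(data) == 0) stop("cannot evaluate on an empty table", call. = FALSE)
  y <- check_outcome(data, outcome)
  res <- fft_apply(model, data)
  cc <- confusion(y, res$decision)
  perf_stats(cc$hi, cc$mi, cc$fa, cc$cr,
             mcu = mean(res$cues_used),
             n_cues = length(cue_columns(data, outcome)))
}

#' Best single-cue threshold rule
#'
#' Scans every unique observed value of a cue as a candidate threshold, in
#' both directions (`>` and `<=`, with the satisfied side predicting
#' positive), and returns the rule maximizing the weighted goal
#' `weight * sens + (1 - weight) * spec` (balanced accuracy at the default
#' `weight = 0.5`). Ties resolve deterministically: higher sensitivity, then
#' lower threshold, then direction `"<="` before `">"`.
#'
#' @param values Numeric cue column (no missing values).
#' @param labels Binary outcome (must contain both classes).
#' @param weight Sensitivity weight in `[0, 1]`.
#' @param cue Optional cue name carried into the result.
#' @return A one-row tibble: `cue`, `direction`, `threshold`, `goal`,
#'   `sens`, `spec`.
#' @examples
#' best_split_for_cue(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
best_split_for_cue <- function(values, labels, weight = 0.5, cue = NA_character_) {
  if (anyNA(values)) {
    stop("missing cue values; impute before scoring splits", call. = FALSE)
  }
  y <- as.integer(labels)
  npos <- sum(y == 1L)
  nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("both classes are required to score a split", call. = FALSE)
  }
  u <- sort(unique(values))
  g <- match(values, u)
  cpos <- cumsum(tabulate(g[y == 1L], nbins = length(u)))
  cneg <- cumsum(tabulate(g[y == 0L], nbins = length(u)))
  sens <- c((npos - cpos) / npos, cpos / npos)      # ">" block, then "<="
  spec <- c(cneg / nneg, (nneg - cneg) / nneg)
  goal <- weight * sens + (1 - weight) * spec
  thr <- c(u, u)
  dirn <- rep(c(">", "<="), each = length(u))
  best <- order(-goal, -sens, thr, dirn)[1]
  tibble::tibble(cue = cue, direction = dirn[best], threshold = thr[best],
                 goal = goal[best], sens = sens[best], spec = spec[best])
}

#' Rank cues by marginal single-split performance
#'
#' Scores each cue independently with [best_split_for_cue()] on the full
#' table and orders cues by decreasing goal (ties: higher sensitivity, lower
#' threshold, alphabetical cue name). This marginal ranking is the first
#' stage of the ifan construction.
#'
#' @param data Labelled cohort tibble.
#' @param cues Cue names to rank; default all non-outcome columns.
#' @param weight Sensitivity weight of the goal.
#' @param outcome Outcome column name.
#' @return A tibble of ranked rules, best first.
#' @export
rank_cues <- function(data, cues = NULL, weight = 0.5, outcome = "pod") {
  y <- check_outcome(data, outcome)
  if (is.null(cues)) cues <- cue_columns(data, outcome)
  missing_cues <- setdiff(cues, names(data))
  if (length(missing_cues) > 0) {
    stop("cue(s) not in table: ", paste(missing_cues, collapse = ", "),
         call. = FALSE)
  }
  ranked <- purrr::map_dfr(cues, function(cue) {
    best_split_for_cue(data[[cue]], y, weight = weight, cue = cue)
  })
  dplyr::arrange(ranked, dplyr::desc(.data$goal), dplyr::desc(.data$sens),
                 .data$threshold, .data$cue)
}

# flip a rule direction (logical negation of the condition)
flip_direction <- function(direction) if (direction == ">") "<=" else ">"

# score an exit-structure assignment over precomputed rule conditions.
# cond: n x k logical matrix, TRUE = rule satisfied (positive side);
# exits: length k-1 vector, 0 = positive exit, 1 = negative exit.
fan_goal <- function(cond, exits, y, npos, nneg, weight) {
  k <- ncol(cond)
  n <- nrow(cond)
  decision <- logical(n)
  remaining <- rep(TRUE, n)
  for (j in seq_len(k - 1)) {
    if (exits[j] == 0) {
      decision[remaining & cond[, j]] <- TRUE
      remaining <- remaining & !cond[, j]
    } else {
      remaining <- remaining & cond[, j]
    }
  }
  decision[remaining] <- cond[remaining, k]
  hi <- sum(decision & y == 1L)
  cr <- sum(!decision & y == 0L)
  sens <- hi / npos
  spec <- cr / nneg
  c(goal = weight * sens + (1 - weight) * spec, sens = sens, spec = spec)
}

#' Build a fast-and-frugal tree with the ifan algorithm
#'
#' ifan ("independent fan") ranks cues by their marginal single-split
#' performance, keeps the top `max_levels` cues in rank order with their
#' marginal thresholds, and exhaustively evaluates the full fan of candidate
#' trees: every depth `k = 1..max_levels` and every one of the `2^(k-1)`
#' assignments of a positive or negative exit to the non-final nodes (the
#' final node always carries both exits). The candidate maximizing the
#' weighted sensitivity/specificity goal on the training set is returned;
#' ties go to the shallower tree, then to the earlier candidate in
#' enumeration order (exit patterns enumerated with positive exits first).
#'
#' @inheritParams rank_cues
#' @param max_levels Maximum tree depth (number of cues), default 5.
#' @return An [fftree()] whose `goal_value` is its training balanced
#'   accuracy and whose `fan` element lists every candidate's depth, exit
#'   pattern, hit rate and false-alarm rate.
#' @export
build_ifan <- function(data, max_levels = 5, weight = 0.5, cues = NULL,
                       outcome = "pod") {
  if (max_levels < 1) stop("max_levels must be >= 1", call. = FALSE)
  y <- check_outcome(data, outcome)
  npos <- sum(y == 1L)
  nneg <- sum(y == 0L)
  ranking <- rank_cues(data, cues, weight, outcome)
  m <- min(max_levels, nrow(ranking))
  cond <- matrix(FALSE, nrow(data), m)
  for (j in seq_len(m)) {
    v <- data[[ranking$cue[j]]]
    cond[, j] <- if (ranking$direction[j] == ">") v > ranking$threshold[j] else v <= ranking$threshold[j]
  }
  best <- NULL
  fan <- list()
  for (k in seq_len(m)) {
    for (a in seq_len(2^(k - 1)) - 1) {
      exits <- if (k > 1) (a %/% 2^(seq_len(k - 1) - 1)) %% 2 else integer(0)
      sc <- fan_goal(cond[, seq_len(k), drop = FALSE], exits, y, npos, nneg, weight)
      fan[[length(fan) + 1]] <- tibble::tibble(
        depth = k, exit_pattern = paste(ifelse(exits == 0, "+", "-"), collapse = ""),
        hr = sc[["sens"]], far = 1 - sc[["spec"]], goal = sc[["goal"]]
      )
      if (is.null(best) || sc[["goal"]] > best$goal) {
        best <- list(k = k, exits = exits, goal = sc[["goal"]],
                     bacc = (sc[["sens"]] + sc[["spec"]]) / 2)
      }
    }
  }
  nodes <- purrr::map_dfr(seq_len(best$k), function(j) {
    r <- ranking[j, ]
    if (j == best$k) {
      tibble::tibble(cue = r$cue, direction = r$direction,
                     threshold = r$threshold, exit = "both")
    } else if (best$exits[j] == 0) {
      tibble::tibble(cue = r$cue, direction = r$direction,
                     threshold = r$threshold, exit = "positive")
    } else {
      tibble::tibble(cue = r$cue, direction = flip_direction(r$direction),
                     threshold = r$threshold, exit = "negative")
    }
  })
  tree <- fftree(nodes, weight = weight, algorithm = "ifan",
                 goal_value = best$bacc)
  tree$fan <- dplyr::bind_rows(fan)
  tree$ranking <- ranking
  tree
}

#' Build a fast-and-frugal tree with the dfan algorithm
#'
#' dfan ("dependent fan") constructs trees recursively: at each node the
#' best single-cue rule is re-computed for every unused cue on the cases
#' that actually reach the node, and the best cue is placed there. Both
#' possible exits (positive and negative) are branched over, each defining a
#' different set of surviving cases and hence a different continuation. All
#' completed candidate trees (one per depth per exit path) are scored on the
#' full training set; the argmax is returned, with a deeper tree adopted
#' only when it strictly improves on the best shallower one, so a fan that
#' finds no improvement at depth `k + 1` yields a truncated depth-`k` tree.
#'
#' @inheritParams build_ifan
#' @param max_levels Maximum tree depth, default 4.
#' @return An [fftree()] with training balanced accuracy in `goal_value`.
#' @export
build_dfan <- function(data, max_levels = 4, weight = 0.5, cues = NULL,
                       outcome = "pod") {
  if (max_levels < 1) stop("max_levels must be >= 1", call. = FALSE)
  y <- check_outcome(data, outcome)
  if (is.null(cues)) cues <- cue_columns(data, outcome)
  npos <- sum(y == 1L)
  nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("both classes are required to build a tree", call. = FALSE)
  }
  best <- NULL

  record <- function(nodes, depth) {
    tree <- fftree(nodes, weight = weight, algorithm = "dfan")
    decision <- fft_apply(tree, data)$decision
    cc <- confusion(y, decision)
    sens <- cc$hi / npos
    spec <- cc$cr / nneg
    goal <- weight * sens + (1 - weight) * spec
    if (is.null(best) || goal > best$goal ||
        (goal == best$goal && depth < best$depth)) {
      best <<- list(nodes = nodes, depth = depth, goal = goal,
                    bacc = (sens + spec) / 2)
    }
  }

  search <- function(rem, used, nodes, depth) {
    yr <- y[rem]
    if (sum(yr == 1L) == 0L || sum(yr == 0L) == 0L) return(invisible())
    avail <- setdiff(cues, used)
    if (length(avail) == 0) return(invisible())
    splits <- purrr::map_dfr(avail, function(cue) {
      best_split_for_cue(data[[cue]][rem], yr, weight = weight, cue = cue)
    })
    splits <- dplyr::arrange(splits, dplyr::desc(.data$goal),
                             dplyr::desc(.data$sens), .data$threshold, .data$cue)
    b <- splits[1, ]
    v <- data[[b$cue]][rem]
    cond <- if (b$direction == ">") v > b$threshold else v <= b$threshold
    record(dplyr::bind_rows(nodes, tibble::tibble(
      cue = b$cue, direction = b$direction, threshold = b$threshold,
      exit = "both"
    )), depth)
    if (depth < max_levels) {
      search(rem[!cond], c(used, b$cue), dplyr::bind_rows(nodes, tibble::tibble(
        cue = b$cue, direction = b$direction, threshold = b$threshold,
        exit = "positive"
      )), depth + 1)
      search(rem[cond], c(used, b$cue), dplyr::bind_rows(nodes, tibble::tibble(
        cue = b$cue, direction = flip_direction(b$direction),
        threshold = b$threshold, exit = "negative"
      )), depth + 1)
    }
    invisible()
  }

  search(seq_len(nrow(data)), character(0), tibble::tibble(), 1)
  fftree(best$nodes, weight = weight, algorithm = "dfan",
         goal_value = best$bacc)
}
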