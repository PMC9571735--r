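# Independent brute-force oracles, deliberately naive plain-R re-derivations
# used to cross-check the vectorized implementations.

# row-by-row tree walk
oracle_classify <- function(nodes, data) {
  vapply(seq_len(nrow(data)), function(r) {
    for (i in seq_len(nrow(nodes))) {
      v <- data[[nodes$cue[i]]][r]
      cond <- if (nodes$direction[i] == ">") v > nodes$threshold[i] else v <= nodes$threshold[i]
      if (nodes$exit[i] == "both") return(as.integer(cond))
      if (cond && nodes$exit[i] == "positive") return(1L)
      if (cond && nodes$exit[i] == "negative") return(0L)
    }
    stop("walk fell through the final node")
  }, integer(1))
}

oracle_goal_of <- function(nodes, data, y, w = 0.5) {
  dec <- oracle_classify(nodes, data)
  sens <- sum(dec == 1 & y == 1) / sum(y == 1)
  spec <- sum(dec == 0 & y == 0) / sum(y == 0)
  w * sens + (1 - w) * spec
}

# enumeration over all thresholds x directions for one cue
oracle_best_rule <- function(v, y, w = 0.5) {
  best <- NULL
  for (t in sort(unique(v))) for (d in c(">", "<=")) {
    pred <- if (d == ">") v > t else v <= t
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    g <- w * sens + (1 - w) * spec
    if (is.null(best) || g > best$goal + 1e-12) {
      best <- list(threshold = t, direction = d, goal = g, sens = sens)
    }
  }
  best
}

# exhaustive ifan oracle: independent per-cue ranking, then every
# rank-ordered prefix x every exit structure; returns the best goal
oracle_ifan_goal <- function(data, y, cues, max_levels, w = 0.5) {
  goals <- vapply(cues, function(cue) oracle_best_rule(data[[cue]], y, w)$goal, 0)
  ord <- cues[order(-goals, cues)]
  m <- min(max_levels, length(ord))
  best <- -Inf
  for (k in seq_len(m)) {
    for (a in seq_len(2^(k - 1)) - 1) {
      exits <- if (k > 1) (a %/% 2^(seq_len(k - 1) - 1)) %% 2 else integer(0)
      nodes <- NULL
      for (j in seq_len(k)) {
        b <- oracle_best_rule(data[[ord[j]]], y, w)
        if (j == k) {
          nodes <- rbind(nodes, data.frame(cue = ord[j], direction = b$direction,
                                           threshold = b$threshold, exit = "both"))
        } else if (exits[j] == 0) {
          nodes <- rbind(nodes, data.frame(cue = ord[j], direction = b$direction,
                                           threshold = b$threshold, exit = "positive"))
        } else {
          nd <- if (b$direction == ">") "<=" else ">"
          nodes <- rbind(nodes, data.frame(cue = ord[j], direction = nd,
                                           threshold = b$threshold, exit = "negative"))
        }
      }
      best <- max(best, oracle_goal_of(nodes, data, y, w))
    }
  }
  best
}

# independent greedy dfan re-derivation: recursive, plain data frames,
# explores every exit path, greedy best cue per node, argmax on full data
# with shallower-tree tie-breaking
oracle_dfan_greedy_goal <- function(data, y, cues, max_levels, w = 0.5) {
  best <- list(goal = -Inf, depth = Inf)
  consider <- function(nodes, depth) {
    g <- oracle_goal_of(nodes, data, y, w)
    if (g > best$goal + 1e-12 ||
        (abs(g - best$goal) <= 1e-12 && depth < best$depth)) {
      best <<- list(goal = g, depth = depth)
    }
  }
  recurse <- function(rem, used, nodes, depth) {
    yr <- y[rem]
    if (sum(yr == 1) == 0 || sum(yr == 0) == 0) return()
    avail <- setdiff(cues, used)
    if (length(avail) == 0) return()
    scored <- lapply(avail, function(cue) {
      c(list(cue = cue), oracle_best_rule(data[[cue]][rem], yr, w))
    })
    goals <- vapply(scored, function(s) s$goal, 0)
    sens <- vapply(scored, function(s) s$sens, 0)
    thr <- vapply(scored, function(s) s$threshold, 0)
    nm <- vapply(scored, function(s) s$cue, "")
    b <- scored[[order(-goals, -sens, thr, nm)[1]]]
    cond <- if (b$direction == ">") data[[b$cue]][rem] > b$threshold else data[[b$cue]][rem] <= b$threshold
    consider(rbind(nodes, data.frame(cue = b$cue, direction = b$direction,
                                     threshold = b$threshold, exit = "both")),
             depth)
    if (depth < max_levels) {
      recurse(rem[!cond], c(used, b$cue),
              rbind(nodes, data.frame(cue = b$cue, direction = b$direction,
                                      threshold = b$threshold, exit = "positive")),
              depth + 1)
      nd <- if (b$direction == ">") "<=" else ">"
      recurse(rem[cond], c(used, b$cue),
              rbind(nodes, data.frame(cue = b$cue, direction = nd,
                                      threshold = b$threshold, exit = "negative")),
              depth + 1)
    }
  }
  recurse(seq_len(nrow(data)), character(0), NULL, 1)
  best$goal
}

# exhaustive search over ALL cue orders x exit structures with per-node
# conditional thresholds (the strongest possible FFT on the training data
# under greedy per-node thresholds)
oracle_all_orders_goal <- function(data, y, cues, max_levels, w = 0.5) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  best <- -Inf
  for (k in seq_len(min(max_levels, length(cues)))) {
    for (s in utils::combn(cues, k, simplify = FALSE)) for (ord in perms(s)) {
      for (a in seq_len(2^(k - 1)) - 1) {
        exits <- if (k > 1) (a %/% 2^(seq_len(k - 1) - 1)) %% 2 else integer(0)
        rem <- rep(TRUE, nrow(data))
        nodes <- NULL
        ok <- TRUE
        for (j in seq_len(k)) {
          yr <- y[rem]
          if (sum(yr == 1) == 0 || sum(yr == 0) == 0) { ok <- FALSE; break }
          b <- oracle_best_rule(data[[ord[j]]][rem], yr, w)
          cond <- if (b$direction == ">") data[[ord[j]]] > b$threshold else data[[ord[j]]] <= b$threshold
          if (j == k) {
            nodes <- rbind(nodes, data.frame(cue = ord[j], direction = b$direction,
                                             threshold = b$threshold, exit = "both"))
          } else if (exits[j] == 0) {
            nodes <- rbind(nodes, data.frame(cue = ord[j], direction = b$direction,
                                             threshold = b$threshold, exit = "positive"))
            rem <- rem & !cond
          } else {
            nd <- if (b$direction == ">") "<=" else ">"
            nodes <- rbind(nodes, data.frame(cue = ord[j], direction = nd,
                                             threshold = b$threshold, exit = "negative"))
            rem <- rem & cond
          }
        }
        if (ok) best <- max(best, oracle_goal_of(nodes, data, y, w))
      }
    }
  }
  best
}

# random small binary-cue instance with both classes present
random_binary_instance <- function(seed, n_range = 10:30, cue_range = 2:4) {
  set.seed(seed)
  n <- sample(n_range, 1)
  nc <- sample(cue_range, 1)
  repeat {
    d <- as.data.frame(matrix(stats::rbinom(n * nc, 1, 0.5), n))
    names(d) <- paste0("c", seq_len(nc))
    y <- stats::rbinom(n, 1, 0.4)
    if (length(unique(y)) == 2) break
  }
  d$pod <- y
  d
}

# a small fully-observed cohort used across tests
toy_cohort <- function() {
  tibble::tibble(
    cci = c(3, 0, 2, 5, 1, 0, 4, 1, 2, 0),
    frailty = c(2, 0, 1, 2, 0, 1, 2, 0, 0, 1),
    age = c(78, 66, 74, 81, 70, 68, 79, 72, 75, 67),
    pod = c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0)
  )
}
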