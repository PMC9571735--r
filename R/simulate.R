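# ---- quantile-transform samplers -------------------------------------------
# Every cue is drawn by pushing one uniform variate through a quantile
# function, so an optional Gaussian copula can correlate cues without
# changing any marginal.

q_levels <- function(levels, probs) {
  stopifnot(length(levels) == length(probs), all(probs >= 0))
  # printed percentages can be off by rounding (e.g. 2.4 + 41.4 + 56.3);
  # renormalize within a 1% tolerance, reject anything worse
  if (abs(sum(probs) - 1) > 0.01) {
    stop("level probabilities must sum to 1", call. = FALSE)
  }
  probs <- probs / sum(probs)
  cuts <- cumsum(probs)[-length(probs)]
  function(p) levels[1L + findInterval(p, cuts)]
}

q_binary <- function(p1) q_levels(c(0, 1), c(1 - p1, p1))

q_discrete_norm <- function(mean, sd, min = -Inf, max = Inf) {
  stopifnot(sd > 0)
  function(p) pmin(pmax(round(stats::qnorm(p, mean, sd)), min), max)
}

q_norm <- function(mean, sd) {
  stopifnot(sd > 0)
  function(p) stats::qnorm(p, mean, sd)
}

# nonnegative integer-valued gamma matched to a mean and SD by method of
# moments; draws rounded to integers, negative mass impossible
q_discrete_gamma <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  shape <- (mean / sd)^2
  scale <- sd^2 / mean
  function(p) pmax(round(stats::qgamma(p, shape = shape, scale = scale)), 0)
}

# log-normal matched to a printed median and quartiles: meanlog = log(median),
# sdlog from the log-IQR (log q3 - log q1 = 2 * qnorm(0.75) * sdlog)
q_lnorm_quartiles <- function(median, q1, q3) {
  stopifnot(q1 > 0, q1 < median, median < q3)
  meanlog <- log(median)
  sdlog <- (log(q3) - log(q1)) / (2 * stats::qnorm(0.75))
  function(p) stats::qlnorm(p, meanlog, sdlog)
}

# zero-inflated gamma (e.g. pack years: never-smokers at 0)
q_zero_gamma <- function(p0, mean, sd) {
  qg <- q_discrete_gamma(mean, sd)
  function(p) {
    out <- numeric(length(p))
    nz <- p >= p0
    out[nz] <- qg((p[nz] - p0) / (1 - p0))
    out
  }
}

#' Default synthetic-cohort generator configuration
#'
#' Class-conditional cue distributions calibrated to the printed patient
#' characteristics of the study cohort (n = 394, POD prevalence 25.1%).
#' Outcome-linked cues follow the printed POD / non-POD marginals:
#' age (median 74 vs 72 years), ASA PS 3--4 (56.6% vs 31.2%), CCI
#' (mean 2.14, SD 1.5 vs mean 1.43, SD 1.6; discretized gamma), frailty
#' levels robust/pre-frail/frail (18.4/51.0/30.6% vs 40.6/49.1/10.3%),
#' surgery site intracranial/major-cavity/peripheral (2.0/67.7/30.3% vs
#' 2.4/41.4/56.3%) and duration of anesthesia (log-normal matched to the
#' printed median and quartiles, 360 [220; 495] vs 157 [100; 260] min). All
#' remaining cues are drawn independently of the outcome from plausible
#' marginals for an elective-surgery population aged 65+.
#'
#' Cues are conditionally independent given the outcome unless a `copula`
#' correlation matrix (row/column names = cue names) is supplied, in which
#' case the named cues share a Gaussian copula on their latent uniforms.
#'
#' @param pod_rate POD prevalence, default 0.251.
#' @param copula Optional correlation matrix for a Gaussian copula across
#'   the named cues; `NULL` (default) leaves cues conditionally independent.
#' @return A `generator_config` list with elements `pod_rate`, `copula` and
#'   `cues` (per cue, quantile functions `pod` and `nonpod`).
#' @seealso [generate_cohort()]
#' @export
generator_config <- function(pod_rate = 0.251, copula = NULL) {
  if (pod_rate < 0 || pod_rate > 1) {
    stop("pod_rate must be in [0, 1]", call. = FALSE)
  }
  both <- function(q) list(pod = q, nonpod = q)
  cues <- list(
    age = list(pod = q_discrete_norm(74, 4.45, min = 65),
               nonpod = q_discrete_norm(72, 5.93, min = 65)),
    sex = both(q_binary(196 / 394)),
    height = both(q_norm(169, 9)),
    bmi = both(q_norm(26.5, 4.2)),
    asa_ps = list(pod = q_levels(1:4, c(0.0868, 0.3472, 0.5094, 0.0566)),
                  nonpod = q_levels(1:4, c(0.1376, 0.5504, 0.2808, 0.0312))),
    cci = list(pod = q_discrete_gamma(2.14, 1.5),
               nonpod = q_discrete_gamma(1.43, 1.6)),
    hypertension = both(q_binary(0.60)),
    coronary_artery_disease = both(q_binary(0.20)),
    diabetes = both(q_binary(0.20)),
    stroke_tia = both(q_binary(0.08)),
    isced = both(q_levels(0:8, c(0.01, 0.03, 0.10, 0.22, 0.18, 0.12, 0.16, 0.13, 0.05))),
    mmse = both(q_discrete_norm(28, 1.8, min = 23, max = 30)),
    cognitive_impairment = both(q_binary(0.15)),
    adl_impaired = both(q_binary(0.10)),
    iadl_impaired = both(q_binary(0.15)),
    mna = both(q_levels(1:3, c(0.03, 0.22, 0.75))),
    frailty = list(pod = q_levels(0:2, c(0.184, 0.510, 0.306)),
                   nonpod = q_levels(0:2, c(0.406, 0.491, 0.103))),
    gds = both(q_discrete_gamma(2.2, 2.2)),
    benzodiazepine_use = both(q_binary(0.08)),
    hazardous_alcohol = both(q_binary(0.12)),
    smoker = both(q_binary(0.15)),
    pack_years = both(q_zero_gamma(0.45, 22, 18)),
    surgery_site = list(pod = q_levels(1:3, c(0.020, 0.677, 0.303)),
                        nonpod = q_levels(1:3, c(0.024, 0.414, 0.563))),
    anesthesia_duration = list(pod = q_lnorm_quartiles(360, 220, 495),
                               nonpod = q_lnorm_quartiles(157, 100, 260)),
    premedication = both(q_binary(0.30))
  )
  if (!is.null(copula)) {
    if (is.null(rownames(copula)) ||
        !all(rownames(copula) %in% names(cues))) {
      stop("copula matrix must carry cue names on its dimnames", call. = FALSE)
    }
  }
  structure(list(pod_rate = pod_rate, cues = cues, copula = copula),
            class = "generator_config")
}

#' Generate a synthetic patient cohort
#'
#' Draws the binary POD outcome as Bernoulli(`pod_rate`), then each cue from
#' its class-conditional distribution in `config`. Deterministic given
#' `seed`.
#'
#' @param n Number of patients (0 gives an empty table).
#' @param seed Integer seed.
#' @param config A [generator_config()].
#' @return A cohort tibble: one column per cue plus the binary `pod`
#'   outcome.
#' @examples
#' cohort <- generate_cohort(200, seed = 1)
#' mean(cohort$pod)
#' @export
generate_cohort <- function(n, seed, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"), n >= 0)
  cue_names <- names(config$cues)
  if (n == 0) {
    cols <- c(stats::setNames(rep(list(numeric(0)), length(cue_names)), cue_names),
              list(pod = integer(0)))
    return(tibble::as_tibble(cols))
  }
  withr::with_seed(as.integer(seed), {
    pod <- stats::rbinom(n, 1, config$pod_rate)
    u <- latent_uniforms(n, cue_names, config$copula)
    cols <- lapply(cue_names, function(cue) {
      q <- config$cues[[cue]]
      ifelse(pod == 1L, q$pod(u[[cue]]), q$nonpod(u[[cue]]))
    })
    names(cols) <- cue_names
    cols$pod <- as.integer(pod)
    tibble::as_tibble(cols)
  })
}

# one uniform per cue per row; cues named in the copula matrix share a
# Gaussian copula, all others are independent
latent_uniforms <- function(n, cue_names, copula) {
  u <- lapply(cue_names, function(cue) stats::runif(n))
  names(u) <- cue_names
  if (!is.null(copula)) {
    nm <- rownames(copula)
    z <- matrix(stats::rnorm(n * length(nm)), n) %*% chol(copula)
    for (j in seq_along(nm)) u[[nm[j]]] <- stats::pnorm(z[, j])
  }
  u
}

#' Generate a cohort with a planted fast-and-frugal tree
#'
#' Draws cue values first, then sets the outcome to the planted tree's own
#' classification of each row, flipped independently with probability
#' `label_noise`. At zero noise the cohort is perfectly separable by the
#' planted tree, which makes these cohorts the ground-truth oracle for
#' structure-recovery checks of the tree builders.
#'
#' @param tree The planted [fftree()].
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param label_noise Flip probability in `[0, 0.5)`.
#' @param cue_samplers Named list of functions `f(n)` drawing each cue;
#'   must cover every tree cue. Defaults to uniform draws spanning each tree
#'   cue's threshold, plus the decoy cues.
#' @param decoys Number of additional outcome-independent noise cues
#'   (`decoy1`, `decoy2`, ...) when `cue_samplers` is `NULL`.
#' @return A cohort tibble with the tree cues, any decoys and the `pod`
#'   outcome.
#' @export
generate_planted <- function(tree, n, seed, label_noise = 0,
                             cue_samplers = NULL, decoys = 2) {
  stopifnot(inherits(tree, "fftree"), n >= 0)
  if (label_noise < 0 || label_noise >= 0.5) {
    stop("label_noise must be in [0, 0.5)", call. = FALSE)
  }
  if (is.null(cue_samplers)) {
    cue_samplers <- lapply(seq_len(nrow(tree$nodes)), function(i) {
      thr <- tree$nodes$threshold[i]
      function(n) stats::runif(n, thr - 1, thr + 1)
    })
    names(cue_samplers) <- tree$nodes$cue
    if (decoys > 0) {
      for (d in seq_len(decoys)) {
        cue_samplers[[paste0("decoy", d)]] <- function(n) stats::runif(n)
      }
    }
  }
  absent <- setdiff(tree$nodes$cue, names(cue_samplers))
  if (length(absent) > 0) {
    stop("no sampler for tree cue(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    cols <- lapply(cue_samplers, function(f) f(n))
    data <- tibble::as_tibble(cols)
    y <- if (n > 0) fft_apply(tree, data)$decision else integer(0)
    flip <- stats::rbinom(n, 1, label_noise) == 1L
    data$pod <- as.integer(ifelse(flip, 1L - y, y))
    data
  })
}

#' Inject missingness into a cohort
#'
#' Independently blanks each targeted cell with probability `rate`; the
#' outcome column is never touched. Used to exercise the imputation rules.
#'
#' @param data Cohort tibble.
#' @param rate Per-cell missingness probability in `[0, 1)`.
#' @param cues Cue columns to target; default all non-outcome columns.
#' @param seed Integer seed.
#' @param outcome Outcome column name (protected).
#' @return The cohort with `NA` holes.
#' @export
inject_missing <- function(data, rate, seed, cues = NULL, outcome = "pod") {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  if (is.null(cues)) cues <- cue_columns(data, outcome)
  unknown <- setdiff(cues, names(data))
  if (length(unknown) > 0) {
    stop("unknown cue(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (outcome %in% cues) stop("the outcome cannot be blanked", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    for (cue in cues) {
      hole <- stats::runif(nrow(data)) < rate
      data[[cue]][hole] <- NA
    }
  })
  data
}
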