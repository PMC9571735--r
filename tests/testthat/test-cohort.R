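test_that("CSV round-trip preserves values, missingness and the outcome", {
  cohort <- generate_cohort(40, seed = 11)
  cohort <- inject_missing(cohort, rate = 0.15, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back[names(cohort)]), as.data.frame(cohort),
               tolerance = 1e-12)
  # a second write reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("the shipped synthetic fixture loads, imputes and classifies", {
  path <- system.file("extdata", "synthetic_cohort_30.csv", package = "frugalpod")
  cohort <- read_cohort(path)
  expect_equal(nrow(cohort), 30)
  expect_setequal(names(cohort), c(pod_cues()$cue, "pod"))
  expect_true(anyNA(cohort))          # ships with holes to exercise imputation
  full <- impute_missing(cohort)
  expect_false(anyNA(full))
  expect_equal(nrow(screen(full, preoperative_tree())$decisions), 30)
})

test_that("read_cohort enforces the outcome contract and drops unknown columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cci,gds,mystery,pod", "1,2,9,0", "3,,8,1", "0,5,7,0", "2,1,6,1"), path)
  expect_warning(cohort <- read_cohort(path), "mystery")
  expect_named(cohort, c("cci", "gds", "pod"))
  expect_equal(nrow(cohort), 4)
  expect_true(is.na(cohort$gds[2]))       # empty cell becomes the missing marker
  expect_identical(cohort$pod, c(0L, 1L, 0L, 1L))

  writeLines(c("cci,gds", "1,2"), path)
  expect_error(read_cohort(path), "outcome")
  writeLines(c("cci,pod", "1,2"), path)
  expect_error(read_cohort(path), "binary")
})

test_that("imputation follows the study rules", {
  base <- generate_cohort(6, seed = 5)
  # median rule cues (odd observed count -> the central order statistic)
  base$gds <- c(1, 3, NA, 5, 2, 8)
  base$mna <- c(NA, 3, 3, 2, 3, 3)
  base$hypertension <- c(NA, 1, 1, 1, 1, NA)
  imp <- impute_missing(base)
  expect_equal(imp$gds[3], 3)             # median of {1,3,5,2,8}
  expect_equal(imp$mna[1], 3)             # constant 3, despite observed values
  expect_equal(imp$hypertension[c(1, 6)], c(0, 0))  # constant 0, not the mode
  # observed cells, outcome and row count untouched
  expect_identical(imp$pod, base$pod)
  expect_equal(imp$gds[-3], base$gds[-3])
  expect_equal(nrow(imp), nrow(base))
})

test_that("even-count medians land on the coding grid and mode ties go low", {
  base <- generate_cohort(4, seed = 5)
  base$gds <- c(1, 2, NA, 8)    # median 2.0 -> stays 2
  base$isced <- c(2, 3, NA, NA) # median 2.5 -> rounds half-up to 3
  base$cci <- c(1, 2, NA, 6)    # integer-coded numeric: median 2
  base$smoker <- c(0, 1, NA, NA)  # tied mode -> smallest value 0
  imp <- impute_missing(base)
  expect_equal(imp$gds[3], 2)
  expect_equal(imp$isced[c(3, 4)], c(3, 3))
  expect_equal(imp$cci[3], 2)
  expect_equal(imp$smoker[c(3, 4)], c(0, 0))
})

test_that("imputation is idempotent, complete, and fatal on all-missing cues", {
  cohort <- inject_missing(generate_cohort(120, seed = 21), rate = 0.25, seed = 9)
  once <- impute_missing(cohort)
  expect_false(anyNA(once))
  expect_identical(impute_missing(once), once)
  # a table with nothing missing is returned unchanged
  clean <- generate_cohort(30, seed = 2)
  expect_identical(impute_missing(clean), clean)
  broken <- clean
  broken$gds <- NA_real_
  expect_error(impute_missing(broken), "gds")
})

test_that("split_half produces the study's equal halves deterministically", {
  cohort <- generate_cohort(394, seed = 1)
  pair <- split_half(cohort, seed = 42)
  expect_equal(nrow(pair$train), 197)
  expect_equal(nrow(pair$test), 197)
  expect_identical(split_half(cohort, seed = 42)$train_idx, pair$train_idx)
  # train and test partition the parent
  expect_identical(
    dplyr::arrange(dplyr::bind_rows(pair$train, pair$test), age, cci,
                   anesthesia_duration),
    dplyr::arrange(cohort, age, cci, anesthesia_duration)
  )
  # odd n: ceiling goes to train
  odd <- split_half(cohort[1:13, ], seed = 7)
  expect_equal(nrow(odd$train), 7)
  expect_equal(nrow(odd$test), 6)
  expect_error(split_half(cohort[1, ], seed = 1), "at least 2")
})

test_that("split_half assigns records to train uniformly across seeds", {
  cohort <- generate_cohort(20, seed = 3)
  counts <- integer(20)
  for (s in 1:1000) {
    counts[split_half(cohort, seed = s)$train_idx] <-
      counts[split_half(cohort, seed = s)$train_idx] + 1L
  }
  # binomial(1000, 0.5) 3-sigma band
  expect_true(all(abs(counts - 500) <= 50))
})
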