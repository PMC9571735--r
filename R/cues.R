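#' The perioperative cue dictionary
#'
#' Returns the default dictionary of predictor variables ("cues") used to
#' stratify older surgical patients by postoperative delirium (POD) risk.
#' The dictionary covers 23 pre-operative cues (demographics, ASA physical
#' status, Charlson Comorbidity Index, named comorbidities, education,
#' cognition, functional status, nutrition, frailty phenotype, depression,
#' medication, alcohol and smoking history, and site of surgery) plus two
#' intraoperative cues (duration of anesthesia, premedication).
#'
#' Each row is one cue specification:
#' \describe{
#'   \item{cue}{cue name; the expected column name in a cohort table.}
#'   \item{kind}{`"numeric"`, `"ordinal"` or `"binary"`.}
#'   \item{role}{`"preoperative"` or `"intraoperative"`.}
#'   \item{impute}{missing-value rule: `"median"`, `"mode"`, or
#'     `"constant"` (with the value in `impute_value`).}
#'   \item{impute_value}{the constant used when `impute == "constant"`,
#'     else `NA`.}
#'   \item{levels}{list column: the ordered legal levels for ordinal and
#'     binary cues; `NULL` for continuous cues. Integer-valued numeric
#'     scores (CCI, MMSE, GDS) carry `integer_coded = TRUE` instead.}
#'   \item{integer_coded}{whether imputed medians are rounded half-up back
#'     onto the cue's integer coding grid.}
#' }
#'
#' Ordinal codings follow the published tree notation: site of surgery
#' 1 = intracranial, 2 = intrathoracic/intra-abdominal/pelvic,
#' 3 = peripheral; frailty 0 = robust, 1 = pre-frail, 2 = frail;
#' ASA PS as integer 1--4. Binary cues are coded 0/1 (1 = present;
#' sex: 1 = female).
#'
#' @param role Optional filter: `"preoperative"` returns the 23
#'   pre-operative cues; `"all"` (default) also includes the two
#'   intraoperative cues.
#' @return A tibble with one row per cue.
#' @examples
#' pod_cues()
#' pod_cues(role = "preoperative")$cue
#' @export
pod_cues <- function(role = c("all", "preoperative")) {
  role <- match.arg(role)
  spec <- function(cue, kind, cue_role, impute, impute_value = NA_real_,
                   levels = NULL, integer_coded = FALSE) {
    tibble::tibble(
      cue = cue, kind = kind, role = cue_role, impute = impute,
      impute_value = impute_value, levels = list(levels),
      integer_coded = integer_coded || kind %in% c("ordinal", "binary")
    )
  }
  d <- dplyr::bind_rows(
    spec("age", "numeric", "preoperative", "median"),
    spec("sex", "binary", "preoperative", "mode", levels = 0:1),
    spec("height", "numeric", "preoperative", "median"),
    spec("bmi", "numeric", "preoperative", "median"),
    spec("asa_ps", "ordinal", "preoperative", "mode", levels = 1:4),
    spec("cci", "numeric", "preoperative", "median", integer_coded = TRUE),
    spec("hypertension", "binary", "preoperative", "constant", 0, levels = 0:1),
    spec("coronary_artery_disease", "binary", "preoperative", "constant", 0, levels = 0:1),
    spec("diabetes", "binary", "preoperative", "constant", 0, levels = 0:1),
    spec("stroke_tia", "binary", "preoperative", "constant", 0, levels = 0:1),
    spec("isced", "ordinal", "preoperative", "median", levels = 0:8),
    spec("mmse", "numeric", "preoperative", "median", integer_coded = TRUE),
    spec("cognitive_impairment", "binary", "preoperative", "constant", 0, levels = 0:1),
    spec("adl_impaired", "binary", "preoperative", "constant", 0, levels = 0:1),
    spec("iadl_impaired", "binary", "preoperative", "constant", 0, levels = 0:1),
    spec("mna", "ordinal", "preoperative", "constant", 3, levels = 1:3),
    spec("frailty", "ordinal", "preoperative", "mode", levels = 0:2),
    spec("gds", "numeric", "preoperative", "median", integer_coded = TRUE),
    spec("benzodiazepine_use", "binary", "preoperative", "mode", levels = 0:1),
    spec("hazardous_alcohol", "binary", "preoperative", "mode", levels = 0:1),
    spec("smoker", "binary", "preoperative", "mode", levels = 0:1),
    spec("pack_years", "numeric", "preoperative", "median"),
    spec("surgery_site", "ordinal", "preoperative", "mode", levels = 1:3),
    spec("anesthesia_duration", "numeric", "intraoperative", "median"),
    spec("premedication", "binary", "intraoperative", "constant", 0, levels = 0:1)
  )
  if (role == "preoperative") d <- d[d$role == "preoperative", ]
  d
}

# internal: cue columns of a cohort table (everything except the outcome)
cue_columns <- function(data, outcome = "pod") {
  setdiff(names(data), outcome)
}

# internal: assert the outcome column exists and is strictly binary 0/1
check_outcome <- function(data, outcome = "pod") {
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  }
  y <- data[[outcome]]
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome column '", outcome, "' must be binary 0/1 with no missing values",
         call. = FALSE)
  }
  invisible(as.integer(y))
}
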