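#' @keywords internal
"_PACKAGE"

.grades <- c("Low", "Inter.", "High")
.architectures <- c("Cribriform", "Solid", "Micropapillary", "Mixed", "ADH")
.lateralities <- c("Left", "Right")

#' Parse a cohort table
#'
#' Reads a tab-delimited cohort table with one row per tissue block, using the
#' column dialect of the packaged 43-sample DCIS cohort fixture: receptor
#' status coded `+` / `-` / `equ` / `NA`, grade in `Low` / `Inter.` / `High`,
#' architecture in `Cribriform` / `Solid` / `Micropapillary` / `Mixed` / `ADH`.
#' `NA` tokens map to missing values; `equ` maps to equivocal HER2 status.
#'
#' A patient may contribute several blocks (e.g. an index lesion and a later
#' recurrence), so `patient_id` values can repeat. Block numbers are only
#' required to be unique within a patient: the source table reuses block
#' numbers across patients from different institutions.
#'
#' @param file Path to a tab-delimited file, or a connection/text to read from.
#' @return A `cohort_table`: a data frame with columns `patient_id`,
#'   `block_id`, `age_years`, `size_cm`, `laterality`, `grade`,
#'   `architecture`, `er`, `her2` (factors with levels positive/negative
#'   (/equivocal)), `n_regions`, `diagnosis_order`.
#' @examples
#' tab <- load_table1_fixture()
#' nrow(tab)                  # 43 specimens
#' count_unique_patients(tab) # 39 patients
#' @seealso [summarize_cohort()], [count_samples_by_size()],
#'   [load_table1_fixture()]
#' @export
parse_cohort_table <- function(file) {
  raw <- utils::read.delim(file, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("patient_id", "block_id", "age_years", "size_cm", "laterality",
                "grade", "architecture", "er", "her2", "n_regions",
                "diagnosis_order")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("cohort table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    return(.as_cohort_table(raw[, required]))
  }

  check_vocab <- function(values, allowed, what) {
    bad <- which(!(values %in% allowed))
    if (length(bad) > 0L) {
      stop(sprintf("row %d: unknown %s token '%s'", bad[1L], what, values[bad[1L]]))
    }
  }
  check_vocab(raw$grade, .grades, "grade")
  check_vocab(raw$architecture, .architectures, "architecture")
  check_vocab(raw$laterality, .lateralities, "laterality")
  check_vocab(raw$er, c("+", "-", "NA"), "ER status")
  check_vocab(raw$her2, c("+", "-", "equ", "NA"), "HER2 status")

  key <- paste(raw$patient_id, raw$block_id, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicate block_id within a patient: ", key[duplicated(key)][1L])
  }

  num_or_na <- function(x, what) {
    out <- suppressWarnings(as.numeric(ifelse(x == "NA", NA_character_, x)))
    bad <- which(is.na(out) & x != "NA")
    if (length(bad) > 0L) {
      stop(sprintf("row %d: non-numeric %s '%s'", bad[1L], what, x[bad[1L]]))
    }
    out
  }
  status <- function(x, equivocal = FALSE) {
    levels <- c("positive", "negative", if (equivocal) "equivocal")
    map <- c("+" = "positive", "-" = "negative", "equ" = "equivocal",
             "NA" = NA_character_)
    factor(unname(map[x]), levels = levels)
  }

  out <- data.frame(
    patient_id = raw$patient_id,
    block_id = raw$block_id,
    age_years = as.integer(num_or_na(raw$age_years, "age")),
    size_cm = num_or_na(raw$size_cm, "size"),
    laterality = factor(raw$laterality, levels = .lateralities),
    grade = factor(raw$grade, levels = .grades),
    architecture = factor(raw$architecture, levels = .architectures),
    er = status(raw$er),
    her2 = status(raw$her2, equivocal = TRUE),
    n_regions = as.integer(num_or_na(raw$n_regions, "region count")),
    diagnosis_order = raw$diagnosis_order,
    stringsAsFactors = FALSE
  )
  if (any(!is.na(out$size_cm) & out$size_cm < 0)) stop("negative size_cm")
  if (any(is.na(out$n_regions)) || any(out$n_regions < 1L)) {
    stop("n_regions must be a positive integer for every row")
  }
  .as_cohort_table(out)
}

.as_cohort_table <- function(df) {
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Serialize a cohort table back to its tab-delimited dialect
#'
#' Inverse of [parse_cohort_table()]: writing and re-parsing round-trips
#' exactly.
#'
#' @param table A `cohort_table`.
#' @param file Path or connection to write to.
#' @export
write_cohort_table <- function(table, file) {
  stopifnot(inherits(table, "cohort_table"))
  out <- data.frame(
    patient_id = table$patient_id,
    block_id = table$block_id,
    age_years = ifelse(is.na(table$age_years), "NA", as.character(table$age_years)),
    size_cm = ifelse(is.na(table$size_cm), "NA", as.character(table$size_cm)),
    laterality = as.character(table$laterality),
    grade = as.character(table$grade),
    architecture = as.character(table$architecture),
    er = .status_token(table$er),
    her2 = .status_token(table$her2),
    n_regions = as.character(table$n_regions),
    diagnosis_order = table$diagnosis_order,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

.status_token <- function(x) {
  map <- c(positive = "+", negative = "-", equivocal = "equ")
  ifelse(is.na(x), "NA", unname(map[as.character(x)]))
}

#' Stratified sample counts for a cohort
#'
#' Counts samples (blocks, not patients) by one of four stratifiers. Samples
#' with a missing value for the chosen stratifier are reported under
#' `unevaluable`, so the returned counts always partition the table.
#'
#' The `grade_group` stratifier reproduces the grouping used for the cohort
#' summary: intermediate- and high-grade lesions form `HG-DCIS`; low-grade
#' lesions are `LG-DCIS` unless their architecture is ADH, which forms its own
#' `ADH` group. For HER2, equivocal calls count in the evaluable denominator
#' but not as positive.
#'
#' @param table A `cohort_table`.
#' @param stratifier One of `"grade_group"`, `"architecture"`, `"er"`, `"her2"`.
#' @return Named integer vector of counts; an `unevaluable` entry is present
#'   whenever any sample has a missing value for the stratifier.
#' @examples
#' summarize_cohort(load_table1_fixture(), "grade_group")
#' # HG-DCIS: 32, LG-DCIS: 9, ADH: 2
#' @export
summarize_cohort <- function(table, stratifier = c("grade_group", "architecture",
                                                   "er", "her2")) {
  stopifnot(inherits(table, "cohort_table"))
  if (nrow(table) == 0L) stop("cohort table is empty")
  stratifier <- match.arg(stratifier)
  values <- switch(stratifier,
    grade_group = {
      gg <- ifelse(table$grade %in% c("Inter.", "High"), "HG-DCIS",
                   ifelse(table$architecture == "ADH", "ADH", "LG-DCIS"))
      factor(gg, levels = c("HG-DCIS", "LG-DCIS", "ADH"))
    },
    architecture = table$architecture,
    er = table$er,
    her2 = table$her2
  )
  counts <- table(values, useNA = "no")
  out <- as.integer(counts)
  names(out) <- names(counts)
  out <- out[out > 0L | names(out) %in% levels(values)]
  n_missing <- sum(is.na(values))
  if (n_missing > 0L) out <- c(out, unevaluable = n_missing)
  out
}

#' Count samples at or above a size threshold
#'
#' Counts samples whose recorded extent is at least `min_size_cm`
#' (inclusive threshold); samples with missing size are excluded from both
#' numerator and denominator.
#'
#' @param table A `cohort_table`.
#' @param min_size_cm Non-negative size threshold in centimetres.
#' @return Integer count.
#' @examples
#' count_samples_by_size(load_table1_fixture(), 4) # 14 extended lesions
#' @export
count_samples_by_size <- function(table, min_size_cm) {
  stopifnot(inherits(table, "cohort_table"))
  if (!is.numeric(min_size_cm) || length(min_size_cm) != 1L || min_size_cm < 0) {
    stop("min_size_cm must be a single non-negative number")
  }
  sum(!is.na(table$size_cm) & table$size_cm >= min_size_cm)
}

#' Count distinct patients in a cohort
#'
#' @param table A `cohort_table`.
#' @return Integer number of distinct `patient_id` values.
#' @export
count_unique_patients <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  length(unique(table$patient_id))
}

#' Load the packaged 43-sample cohort fixture
#'
#' Returns the clinical and pathological table of the 43 pre-invasive breast
#' specimens (39 patients) that anchors the package examples: age, lesion
#' size, laterality, grade, architecture, ER/HER2 status, number of
#' microdissected regions and diagnosis order per block.
#'
#' @return A `cohort_table` with 43 rows.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_cohort.tsv", package = "dcisatlas",
                      mustWork = TRUE)
  tab <- parse_cohort_table(path)
  if (nrow(tab) != 43L) {
    stop("packaged cohort fixture is corrupted: expected 43 rows, found ", nrow(tab))
  }
  tab
}
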