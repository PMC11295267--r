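# Canonical column layout of the "reduced" admissions table (one row per
# AIH). A column dictionary maps other layouts onto these names.
REDUCED_FIELDS <- c(
  "aih_number", "cnes", "aih_type", "dob", "age_years", "sex", "race_color",
  "postcode", "admission_date", "discharge_date", "billing_reason",
  "primary_procedure", "icu_days"
)

DEFAULT_DIAGNOSIS_FIELDS <- c(
  "diag_primary", "diag_secondary",
  paste0("diag_secondary", 1:9),
  "diag_associated", "diag_notification", "diag_death"
)

rename_by_dictionary <- function(df, dictionary) {
  if (is.null(dictionary)) return(df)
  stopifnot(is.character(dictionary), !is.null(names(dictionary)))
  for (canonical in names(dictionary)) {
    physical <- dictionary[[canonical]]
    if (!physical %in% names(df)) {
      stop("dictionary column not found in file: ", physical)
    }
    names(df)[names(df) == physical] <- canonical
  }
  df
}

parse_date <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  as.Date(x, format = "%Y-%m-%d", optional = TRUE)
}

# lenient 10-digit normalization for data (not config): invalid -> NA + flag
normalize_procedure_lenient <- function(raw) {
  x <- gsub("[^0-9]", "", trimws(as.character(raw)))
  x[is.na(x) | x == ""] <- NA_character_
  bad <- !is.na(x) & nchar(x) != 10L
  x[bad] <- NA_character_
  list(code = x, bad = bad)
}

#' Read the reduced admissions table
#'
#' Parses a delimited file with one row per admission authorization (AIH).
#' Rows that cannot be trusted — unparseable or inverted dates, malformed
#' procedure codes, duplicated AIH numbers — are quarantined with a reason,
#' never silently dropped.
#'
#' @param path delimited text file (UTF-8).
#' @param dictionary optional named character vector mapping canonical field
#'   names (names) to physical column names in the file (values); `NULL` if
#'   the file already uses the canonical layout.
#' @param sep field separator (`","` or `";"`).
#' @param diagnosis_fields diagnosis columns to carry (normalized as ICD).
#' @return list with `records` (parsed data frame) and `quarantine`
#'   (offending raw rows plus a `quarantine_reason` column).
#' @export
read_reduced <- function(path, dictionary = NULL, sep = ",",
                         diagnosis_fields = DEFAULT_DIAGNOSIS_FIELDS) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           na.strings = character(), check.names = FALSE,
                           fileEncoding = "UTF-8")
  raw <- rename_by_dictionary(raw, dictionary)

  mandatory <- c("aih_number", "cnes", "admission_date")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss)) stop("reduced table missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  for (f in setdiff(c(REDUCED_FIELDS, diagnosis_fields), names(raw))) {
    raw[[f]] <- ""
  }

  df <- data.frame(
    aih_number = trimws(raw$aih_number),
    cnes = trimws(raw$cnes),
    aih_type = suppressWarnings(as.integer(trimws(raw$aih_type))),
    dob = parse_date(raw$dob),
    age_years = suppressWarnings(as.integer(trimws(raw$age_years))),
    sex = trimws(raw$sex),
    race_color = trimws(raw$race_color),
    postcode = trimws(raw$postcode),
    admission_date = parse_date(raw$admission_date),
    discharge_date = parse_date(raw$discharge_date),
    billing_reason = trimws(raw$billing_reason),
    icu_days = suppressWarnings(as.integer(trimws(raw$icu_days))),
    stringsAsFactors = FALSE
  )
  df$icu_days[is.na(df$icu_days)] <- 0L
  proc <- normalize_procedure_lenient(raw$primary_procedure)
  df$primary_procedure <- proc$code
  for (f in diagnosis_fields) df[[f]] <- normalize_icd(raw[[f]])
  df$source_row <- seq_len(nrow(df))

  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, why) {
    cond <- !is.na(cond) & cond
    reason[is.na(reason) & cond] <<- why
  }
  flag(trimws(raw$admission_date) != "" & is.na(df$admission_date),
       "unparseable admission_date")
  flag(trimws(raw$discharge_date) != "" & is.na(df$discharge_date),
       "unparseable discharge_date")
  flag(trimws(raw$dob) != "" & is.na(df$dob), "unparseable dob")
  flag(is.na(df$admission_date), "missing admission_date")
  flag(!is.na(df$discharge_date) & df$discharge_date < df$admission_date,
       "discharge before admission")
  flag(proc$bad, "malformed primary_procedure")
  flag(df$icu_days < 0, "negative icu_days")
  flag(duplicated(df$aih_number), "duplicate aih_number")

  bad <- !is.na(reason)
  quarantine <- cbind(raw[bad, , drop = FALSE],
                      quarantine_reason = reason[bad])
  if (any(bad)) {
    warning(sum(bad), " row(s) quarantined while reading reduced table (",
            paste(unique(reason[bad]), collapse = "; "), ")")
  }
  list(records = df[!bad, , drop = FALSE], quarantine = quarantine)
}

#' Read the professional-services table
#'
#' One row per professional act, keyed by AIH number.
#'
#' @inheritParams read_reduced
#' @return list with `acts` (data frame: `aih_number`, `procedure`) and
#'   `quarantine`.
#' @export
read_professional_acts <- function(path, dictionary = NULL, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           na.strings = character(), check.names = FALSE,
                           fileEncoding = "UTF-8")
  raw <- rename_by_dictionary(raw, dictionary)
  miss <- setdiff(c("aih_number", "procedure"), names(raw))
  if (length(miss)) stop("professional-services table missing column(s): ",
                         paste(miss, collapse = ", "))
  proc <- normalize_procedure_lenient(raw$procedure)
  bad <- proc$bad | is.na(proc$code) | trimws(raw$aih_number) == ""
  if (any(bad)) {
    warning(sum(bad), " act row(s) quarantined (missing key or malformed code)")
  }
  list(
    acts = data.frame(aih_number = trimws(raw$aih_number)[!bad],
                      procedure = proc$code[!bad],
                      stringsAsFactors = FALSE),
    quarantine = raw[bad, , drop = FALSE]
  )
}

#' Stage-1 population filter
#'
#' Keeps type-1 AIHs of women aged 10 to 49 (inclusive) at admission. Age is
#' computed from date of birth when available (it is also a linkage key, so
#' it is the more reliable field); the recorded age is used only when date of
#' birth is missing. Records where neither is available, or where sex is
#' missing, are excluded and counted.
#'
#' @param records data frame from [read_reduced()].
#' @param age_range inclusive age bounds in completed years.
#' @return list with `records` (kept rows, plus an `age_at_admission`
#'   column) and `exclusions` (named counts by cause).
#' @export
stage1_filter <- function(records, age_range = c(10L, 49L)) {
  age <- ifelse(
    !is.na(records$dob),
    as.integer(floor(as.numeric(records$admission_date - records$dob) / 365.25)),
    records$age_years
  )
  cause <- rep(NA_character_, nrow(records))
  set <- function(cond, why) {
    cond <- !is.na(cond) & cond
    cause[is.na(cause) & cond] <<- why
  }
  set(is.na(records$aih_type) | records$aih_type != 1L, "not_type1")
  set(is.na(records$sex) | records$sex == "", "sex_missing")
  set(records$sex != "F", "not_female")
  set(is.na(age), "age_unknown")
  set(age < age_range[1] | age > age_range[2], "age_out_of_range")

  keep <- is.na(cause)
  out <- records[keep, , drop = FALSE]
  out$age_at_admission <- age[keep]
  excl <- table(factor(cause[!keep],
                       levels = c("not_type1", "sex_missing", "not_female",
                                  "age_unknown", "age_out_of_range")))
  list(records = out, exclusions = c(excl))
}

#' Join professional acts to admissions
#'
#' @param records data frame of AIH rows (must have `aih_number`).
#' @param acts data frame of acts (`aih_number`, `procedure`, normalized).
#' @return list with `acts_by_aih` (named list: every AIH number in
#'   `records` mapped to its unique set of act codes, possibly empty),
#'   `orphans` (acts whose AIH number has no admission row) and
#'   `orphan_count`.
#' @export
attach_acts <- function(records, acts) {
  known <- unique(records$aih_number)
  orphan <- !(acts$aih_number %in% known)
  kept <- acts[!orphan, , drop = FALSE]
  by_aih <- lapply(split(kept$procedure, kept$aih_number), unique)
  empty <- setdiff(known, names(by_aih))
  by_aih[empty] <- list(character())
  list(acts_by_aih = by_aih[known],
       orphans = acts[orphan, , drop = FALSE],
       orphan_count = sum(orphan))
}
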