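# The eleven severe-morbidity criteria (seven diagnoses, four procedures),
# in report order.
CRITERIA <- c(
  "severe_preeclampsia", "eclampsia", "hellp", "abruptio_placentae",
  "hemorrhage", "uterine_rupture", "ectopic_pregnancy",
  "hysterectomy", "laparotomy", "transfusion", "icu"
)

# Billing-reason tokens of the AIH layout; every one must map to exactly one
# discharge category.
BILLING_TOKENS <- c("1", "2", "3", "4", "5",
                    "6.1", "6.2", "6.3", "6.4", "6.5", "6.6", "6.7", "")

REASON_LEVELS <- c("delivery", "abortion", "pregnancy_complication",
                   "puerperium_complication", "other", "missing")
DISCHARGE_LEVELS <- c("routine", "administrative", "continuing_stay",
                      "death", "transfer", "blank")

# Billing-reason token meaning "continuing inpatient stay": the AIH was
# closed because a new AIH had to be issued for the same hospitalization.
CONTINUING_STAY_TOKEN <- "2"

#' Normalize an ICD-10 code
#'
#' Uppercases and strips dots and whitespace. Empty or whitespace-only input
#' signals "no diagnosis recorded" and becomes `NA`.
#'
#' @param raw character vector of raw ICD codes.
#' @return character vector of normalized codes (`NA` where no code).
#' @examples
#' normalize_icd(c("O14.1", "o141 ", "", "Z513"))
#' @export
normalize_icd <- function(raw) {
  x <- toupper(gsub("[. ]", "", trimws(as.character(raw))))
  x[is.na(x) | x == ""] <- NA_character_
  x
}

#' Normalize a SIGTAP procedure code
#'
#' Procedure codes are printed either as bare 10-digit strings or punctuated
#' as `NN.NN.NN.NNN-N`; both normalize to the 10-digit canonical form.
#'
#' @param raw character vector of raw procedure codes.
#' @param allow_empty if `TRUE`, empty input becomes `NA` instead of an error.
#' @return character vector of 10-digit codes.
#' @examples
#' normalize_procedure("04.11.02.004-8")
#' @export
normalize_procedure <- function(raw, allow_empty = FALSE) {
  x <- gsub("[^0-9]", "", trimws(as.character(raw)))
  empty <- is.na(x) | x == ""
  if (any(empty)) {
    if (!allow_empty) {
      stop("empty procedure code in: ",
           paste(utils::head(raw[empty], 3), collapse = ", "))
    }
    x[empty] <- NA_character_
  }
  bad <- !is.na(x) & nchar(x) != 10L
  if (any(bad)) {
    stop("procedure code(s) not 10 digits after normalization: ",
         paste(unique(raw[bad]), collapse = ", "))
  }
  x
}

# Expand an ICD token or range ("O00-O08", "O30", "P95") into 3-character
# prefix patterns. A prefix pattern matches the 3-character category and any
# 4-character subcategory under it.
expand_icd_range <- function(token) {
  token <- normalize_icd(token)
  if (is.na(token)) stop("empty ICD range token")
  if (grepl("-", token, fixed = TRUE)) {
    parts <- strsplit(token, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed ICD range: ", token)
    lo <- parts[1]; hi <- parts[2]
    if (substr(lo, 1, 1) != substr(hi, 1, 1) ||
        !grepl("^[A-Z][0-9]{2}$", lo) || !grepl("^[A-Z][0-9]{2}$", hi)) {
      stop("malformed ICD range: ", token)
    }
    lo_n <- as.integer(substr(lo, 2, 3)); hi_n <- as.integer(substr(hi, 2, 3))
    if (hi_n < lo_n) stop("descending ICD range: ", token)
    sprintf("%s%02d", substr(lo, 1, 1), lo_n:hi_n)
  } else {
    if (!grepl("^[A-Z][0-9A-Z]{0,3}$", token)) {
      stop("malformed ICD pattern: ", token)
    }
    token
  }
}

#' Build a code set for matching
#'
#' @param exact character vector of codes matched by equality.
#' @param prefix character vector of prefixes; a prefix matches any code that
#'   extends it (so `"O75"` matches `"O75"` and `"O751"`).
#' @return an object of class `codeset`.
#' @export
codeset <- function(exact = character(), prefix = character()) {
  structure(list(exact = unique(exact), prefix = unique(prefix)),
            class = "codeset")
}

#' Match codes against a code set
#'
#' @param codes character vector of normalized codes (`NA` allowed, never
#'   matches).
#' @param set a [codeset()].
#' @return logical vector, same length as `codes`.
#' @export
match_codes <- function(codes, set) {
  codes <- as.character(codes)
  stopifnot(inherits(set, "codeset"))
  out <- codes %in% set$exact
  if (length(set$prefix)) {
    ok <- !is.na(codes)
    for (p in set$prefix) {
      out[ok] <- out[ok] | startsWith(codes[ok], p)
    }
  }
  out & !is.na(codes)
}

icd_codeset <- function(tokens, mode = c("prefix", "exact")) {
  mode <- match.arg(mode)
  pats <- unlist(lapply(tokens, expand_icd_range), use.names = FALSE)
  if (mode == "prefix") codeset(prefix = pats) else codeset(exact = pats)
}

#' Load a classification rulebook
#'
#' Reads and validates the declarative codebook driving obstetric
#' identification, reason-for-hospitalization and discharge-type
#' classification, and the eleven severe-morbidity criteria. The packaged
#' default configuration carries the operational definitions used for
#' maternal-morbidity surveillance on AIH claims.
#'
#' @param config path to a YAML document, or an already-parsed list.
#' @return an object of class `rulebook`.
#' @seealso [default_rulebook()]
#' @export
load_rulebook <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("rulebook config must be a file path or a list")

  need <- c("diagnosis_fields", "obstetric", "reason", "discharge", "criteria")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("rulebook config missing section(s): ",
                         paste(miss, collapse = ", "))

  diagnosis_fields <- as.character(cfg$diagnosis_fields)
  if (length(diagnosis_fields) < 1L) stop("diagnosis_fields must be non-empty")

  obstetric <- list(
    icd = icd_codeset(cfg$obstetric$icd, "prefix"),
    procedures = normalize_procedure(cfg$obstetric$procedures)
  )

  reason_names <- c("abortion", "delivery", "pregnancy_complication",
                    "puerperium_complication")
  miss <- setdiff(reason_names, names(cfg$reason))
  if (length(miss)) stop("rulebook missing reason rule(s): ",
                         paste(miss, collapse = ", "))
  reason_rules <- lapply(cfg$reason[reason_names], function(r) {
    list(
      primary_icd = icd_codeset(r$primary_icd, "prefix"),
      procedures = if (is.null(r$procedures)) character()
                   else normalize_procedure(r$procedures),
      any_other_icd = isTRUE(r$any_other_icd)
    )
  })

  # discharge map: token -> category, every billing token exactly once
  discharge_map <- character()
  for (cat in names(cfg$discharge)) {
    if (!cat %in% DISCHARGE_LEVELS) {
      stop("unknown discharge category in rulebook: ", cat)
    }
    toks <- as.character(cfg$discharge[[cat]])
    discharge_map[toks] <- cat
  }
  unknown <- setdiff(names(discharge_map), BILLING_TOKENS)
  if (length(unknown)) stop("unknown billing-reason token(s) in rulebook: ",
                            paste(shQuote(unknown), collapse = ", "))
  miss <- setdiff(BILLING_TOKENS, names(discharge_map))
  if (length(miss)) stop("billing-reason token(s) not mapped: ",
                         paste(shQuote(miss), collapse = ", "))
  n_maps <- vapply(cfg$discharge, length, 1L)
  if (sum(n_maps) != length(BILLING_TOKENS)) {
    stop("a billing-reason token is mapped to more than one discharge category")
  }

  miss <- setdiff(CRITERIA, names(cfg$criteria))
  if (length(miss)) stop("rulebook missing criterion/criteria: ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(cfg$criteria), CRITERIA)
  if (length(extra)) stop("unknown criterion/criteria in rulebook: ",
                          paste(extra, collapse = ", "))
  criteria <- lapply(cfg$criteria[CRITERIA], function(cr) {
    icd <- if (is.null(cr$icd)) character() else normalize_icd(cr$icd)
    if (anyNA(icd)) stop("empty ICD code in criterion definition")
    bad <- !grepl("^[A-Z][0-9A-Z]{2,3}$", icd)
    if (any(bad)) stop("malformed criterion ICD code(s): ",
                       paste(icd[bad], collapse = ", "))
    list(
      icd = codeset(exact = icd),
      procedures = if (is.null(cr$procedures)) character()
                   else normalize_procedure(cr$procedures),
      uses_icu_days = isTRUE(cr$uses_icu_days)
    )
  })
  no_evidence <- vapply(criteria, function(cr) {
    length(cr$icd$exact) == 0L && length(cr$procedures) == 0L &&
      !cr$uses_icu_days
  }, TRUE)
  if (any(no_evidence)) stop("criterion with no evidence rule: ",
                             paste(CRITERIA[no_evidence], collapse = ", "))

  structure(list(
    name = if (is.null(cfg$name)) "rulebook" else cfg$name,
    diagnosis_fields = diagnosis_fields,
    obstetric = obstetric,
    reason_rules = reason_rules,
    discharge_map = discharge_map,
    criteria = criteria,
    config = cfg
  ), class = "rulebook")
}

#' The packaged default rulebook
#'
#' @return the validated `rulebook` built from the packaged default
#'   configuration (`inst/extdata/box1_default.yaml`).
#' @export
default_rulebook <- function() {
  path <- system.file("extdata", "box1_default.yaml", package = "sihvalid",
                      mustWork = TRUE)
  load_rulebook(path)
}

#' Serialize a rulebook back to YAML
#'
#' Writes the configuration the rulebook was loaded from; reloading the file
#' reproduces an identical rulebook.
#'
#' @param rb a `rulebook`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rulebook <- function(rb, path) {
  stopifnot(inherits(rb, "rulebook"))
  yaml::write_yaml(rb$config, path)
  invisible(path)
}

#' @export
print.rulebook <- function(x, ...) {
  cat("<rulebook>", x$name, "\n")
  cat("  diagnosis fields:", length(x$diagnosis_fields), "\n")
  cat("  obstetric procedures:", length(x$obstetric$procedures), "\n")
  cat("  criteria:", length(x$criteria), "\n")
  invisible(x)
}
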