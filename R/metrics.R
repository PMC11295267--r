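# Diagnostic-validity metrics: record coverage, confusion tables,
# sensitivity, specificity, likelihood ratios with interpretation bands, and
# the stratified report tables (all hospitals together, public and private
# separately).

#' Round half away from zero
#'
#' The rounding convention used for all printed percentages and likelihood
#' ratios (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Record coverage of the claims system
#'
#' Claims-side hospitalization count as a percentage of the
#' reference-standard count. Coverage of at least 90% is deemed adequate;
#' above 110% flags over-recording.
#'
#' @param n_index claims-side count.
#' @param n_ref reference-standard count (> 0).
#' @param adequacy_threshold,over_threshold percentage thresholds.
#' @return list of class `coverage_result`: `n_index`, `n_ref`, `pct`
#'   (one decimal, half away from zero), `adequate`, `over_recording`.
#' @examples
#' coverage(32212, 33867)$pct  # 95.1
#' @export
coverage <- function(n_index, n_ref, adequacy_threshold = 90,
                     over_threshold = 110) {
  if (is.na(n_ref) || n_ref <= 0) {
    stop("coverage undefined: reference count must be positive")
  }
  pct <- round_half_away(100 * n_index / n_ref, 1)
  structure(list(n_index = n_index, n_ref = n_ref, pct = pct,
                 adequate = pct >= adequacy_threshold,
                 over_recording = pct > over_threshold),
            class = "coverage_result")
}

#' Confusion counts of paired flags
#'
#' @param ref_flags logical vector: reference-standard (true) condition.
#' @param index_flags logical vector, same length, aligned by linked pair:
#'   condition flagged in claims.
#' @return list of class `confusion_table` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(ref_flags, index_flags) {
  if (length(ref_flags) != length(index_flags)) {
    stop("flag vectors differ in length")
  }
  ref_flags <- as.logical(ref_flags)
  index_flags <- as.logical(index_flags)
  structure(list(
    tp = sum(ref_flags & index_flags),
    fp = sum(!ref_flags & index_flags),
    fn = sum(ref_flags & !index_flags),
    tn = sum(!ref_flags & !index_flags)
  ), class = "confusion_table")
}

#' Sensitivity, specificity and likelihood ratios
#'
#' Positive LR = sensitivity / (1 - specificity); negative LR =
#' (1 - sensitivity) / specificity. With no false positives the positive LR
#' is infinite (rendered as an em-dash in reports); with no true negatives
#' the negative LR is undefined.
#'
#' @param ct a `confusion_table`, or `sens`/`spec` proportions given
#'   directly (in `[0, 1]`).
#' @param sens,spec proportions, used when `ct` is `NULL` (e.g. to recompute
#'   ratios from printed sensitivity/specificity pairs).
#' @return list of class `validity_result`: `sens`, `spec` (proportions),
#'   `lr_pos`, `lr_neg`, interpretation `band_pos`, `band_neg`, and the
#'   counts when a confusion table was given.
#' @examples
#' validity(sens = 0.380, spec = 0.974)$lr_neg  # ~0.64
#' @export
validity <- function(ct = NULL, sens = NULL, spec = NULL) {
  if (!is.null(ct)) {
    stopifnot(inherits(ct, "confusion_table"))
    if (ct$tp + ct$fn == 0) stop("no reference positives: sensitivity undefined")
    if (ct$fp + ct$tn == 0) stop("no reference negatives: specificity undefined")
    sens <- ct$tp / (ct$tp + ct$fn)
    spec <- ct$tn / (ct$fp + ct$tn)
  }
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  lr_pos <- if (spec == 1) Inf else sens / (1 - spec)
  lr_neg <- if (spec == 0) NA_real_ else (1 - sens) / spec
  bands <- interpret(lr_pos, lr_neg)
  structure(list(sens = sens, spec = spec, lr_pos = lr_pos, lr_neg = lr_neg,
                 band_pos = bands$band_pos, band_neg = bands$band_neg,
                 counts = ct),
            class = "validity_result")
}

#' Interpretation bands for likelihood ratios
#'
#' Bands are assigned on the value rounded to its printing precision
#' (positive LR one decimal, negative LR two decimals): positive LR at least
#' 10 is strong, 5-9.9 moderate, 2-4.9 weak, 1-1.9 very weak; negative LR
#' up to 0.10 is strong, 0.11-0.20 moderate, 0.21-0.50 weak, 0.51-1 very
#' weak. An infinite positive LR (no false positives) is strong.
#'
#' @param lr_pos,lr_neg likelihood ratios (`NA` allowed).
#' @return list with `band_pos` and `band_neg` labels (`NA` when the ratio
#'   is unavailable, `"unclassified"` outside the defined bands).
#' @export
interpret <- function(lr_pos = NA, lr_neg = NA) {
  band_pos <- if (is.na(lr_pos)) {
    NA_character_
  } else if (is.infinite(lr_pos)) {
    "strong"
  } else {
    v <- round_half_away(lr_pos, 1)
    if (v >= 10) "strong"
    else if (v >= 5) "moderate"
    else if (v >= 2) "weak"
    else if (v >= 1) "very weak"
    else "unclassified"
  }
  band_neg <- if (is.na(lr_neg)) {
    NA_character_
  } else {
    v <- round_half_away(lr_neg, 2)
    if (v <= 0.10) "strong"
    else if (v <= 0.20) "moderate"
    else if (v <= 0.50) "weak"
    else if (v <= 1) "very weak"
    else "unclassified"
  }
  list(band_pos = band_pos, band_neg = band_neg)
}

format_lr_pos <- function(x) {
  if (is.na(x) || is.infinite(x)) "–"
  else formatC(round_half_away(x, 1), format = "f", digits = 1, big.mark = ",")
}

format_lr_neg <- function(x) {
  if (is.na(x)) "–"
  else formatC(round_half_away(x, 2), format = "f", digits = 2)
}

#' Exclude hospitals with poorly filled reason-for-hospitalization
#'
#' Hospitals where the reason is missing for more than `threshold` percent
#' of reference hospitalizations are dropped from the reason-comparison
#' analysis (only).
#'
#' @param reference data frame with `cnes` and a `reason` column (`NA` or
#'   `""` = missing).
#' @param threshold percentage; strictly above it excludes.
#' @return character vector of kept `cnes` codes.
#' @export
missingness_exclusion <- function(reference, threshold = 10) {
  missing <- is.na(reference$reason) | reference$reason == ""
  pct <- tapply(missing, reference$cnes, mean) * 100
  names(pct)[pct <= threshold]
}
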