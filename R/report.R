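# Stratified report tables: coverage per hospital and stratum, the reason /
# discharge distribution comparison, and the per-criterion validity table
# with its four evidence-channel count columns.

STRATA <- c("public", "private", "total")

pct1 <- function(num, den) {
  ifelse(den > 0, round_half_away(100 * num / den, 1), NA_real_)
}

#' Coverage report per hospital and stratum
#'
#' @param index_by_cnes named integer: claims-side obstetric episode count
#'   per facility code.
#' @param ref_by_cnes named integer: reference-standard hospitalization
#'   count per facility code.
#' @param type_by_cnes named character (`"public"`/`"private"`) per facility.
#' @param adequacy_threshold,over_threshold percentage thresholds.
#' @return list with `per_hospital` and `per_stratum` data frames (counts,
#'   coverage percent, adequacy and over-recording flags, and — per stratum —
#'   the share of hospitals below adequacy and above over-recording).
#' @export
coverage_report <- function(index_by_cnes, ref_by_cnes, type_by_cnes,
                            adequacy_threshold = 90, over_threshold = 110) {
  cnes <- names(ref_by_cnes)
  n_idx <- ifelse(is.na(index_by_cnes[cnes]), 0L, index_by_cnes[cnes])
  per_hospital <- data.frame(
    cnes = cnes,
    hospital_type = unname(type_by_cnes[cnes]),
    n_index = as.integer(n_idx),
    n_ref = as.integer(ref_by_cnes),
    stringsAsFactors = FALSE
  )
  per_hospital$pct <- pct1(per_hospital$n_index, per_hospital$n_ref)
  per_hospital$adequate <- per_hospital$pct >= adequacy_threshold
  per_hospital$over_recording <- per_hospital$pct > over_threshold

  strat_rows <- lapply(STRATA, function(s) {
    sel <- if (s == "total") rep(TRUE, nrow(per_hospital))
           else per_hospital$hospital_type == s
    ni <- sum(per_hospital$n_index[sel]); nr <- sum(per_hospital$n_ref[sel])
    cv <- coverage(ni, nr, adequacy_threshold, over_threshold)
    data.frame(
      stratum = s, n_index = ni, n_ref = nr, pct = cv$pct,
      adequate = cv$adequate, over_recording = cv$over_recording,
      pct_hospitals_below_adequate =
        pct1(sum(!per_hospital$adequate[sel]), sum(sel)),
      pct_hospitals_over_recording =
        pct1(sum(per_hospital$over_recording[sel]), sum(sel)),
      stringsAsFactors = FALSE
    )
  })
  list(per_hospital = per_hospital,
       per_stratum = do.call(rbind, strat_rows))
}

distribution_pct <- function(values, levels, den = length(values)) {
  counts <- table(factor(values, levels = levels))
  data.frame(category = levels, n = as.integer(counts),
             pct = pct1(as.integer(counts), den),
             stringsAsFactors = FALSE)
}

#' Reason and discharge distribution comparison
#'
#' Builds the claims-versus-reference distribution of reason for
#' hospitalization and discharge type per stratum. For the reason
#' comparison, hospitals where the reference reason is missing beyond the
#' threshold are excluded from both sides; reference stays with a missing
#' reason at kept hospitals are shown as `missing`.
#'
#' @param reference reference table (`cnes`, `hospital_type`, `reason`,
#'   `discharge_type`).
#' @param claims data frame of classified obstetric episodes (`cnes`,
#'   `reason`, `discharge`).
#' @param missing_threshold percentage for [missingness_exclusion()].
#' @return list with `reason` and `discharge` data frames (stratum, source,
#'   category, n, pct).
#' @export
reason_discharge_table <- function(reference, claims,
                                   missing_threshold = 10) {
  type_by_cnes <- tapply(reference$hospital_type, reference$cnes,
                         function(x) x[1])
  claims$hospital_type <- unname(type_by_cnes[claims$cnes])
  kept <- missingness_exclusion(reference, missing_threshold)

  one <- function(values, cnes, types, levels, source, keep_cnes = NULL) {
    rows <- lapply(STRATA, function(s) {
      sel <- if (s == "total") rep(TRUE, length(values)) else types == s
      sel <- sel & !is.na(types)
      if (!is.null(keep_cnes)) sel <- sel & cnes %in% keep_cnes
      d <- distribution_pct(values[sel], levels)
      d$stratum <- s; d$source <- source
      d
    })
    do.call(rbind, rows)
  }
  reason_levels <- c(REASON_LEVELS, NA)
  ref_reason <- reference$reason
  ref_reason[!is.na(ref_reason) & ref_reason == ""] <- "missing"
  ref_reason[is.na(ref_reason)] <- "missing"
  reason <- rbind(
    one(ref_reason, reference$cnes, reference$hospital_type,
        REASON_LEVELS, "reference", kept),
    one(claims$reason, claims$cnes, claims$hospital_type,
        REASON_LEVELS, "claims", kept)
  )
  discharge <- rbind(
    one(reference$discharge_type, reference$cnes, reference$hospital_type,
        DISCHARGE_LEVELS, "reference"),
    one(claims$discharge, claims$cnes, claims$hospital_type,
        DISCHARGE_LEVELS, "claims")
  )
  list(reason = reason, discharge = discharge)
}

#' Per-criterion validity table over linked morbidity pairs
#'
#' For each criterion and stratum: reference-positive count and frequency,
#' claims-side counts by evidence channel (diagnosis fields, primary
#' procedure, professional acts, and their union) with frequencies over the
#' linked denominator, sensitivity, specificity, likelihood ratios and
#' interpretation bands. Strata or criteria with no reference positives keep
#' their row with blank sensitivity, as frequency reporting still applies.
#'
#' The ICU criterion's stay-days evidence (a reduced-table variable) is
#' reported in the `ICD` column slot, as the reduced database is its source.
#'
#' @param ref_flags logical matrix (linked pairs x criteria): reference
#'   condition.
#' @param claim_flags list of logical matrices per channel (linked pairs x
#'   criteria), as produced by [classify_episodes()] and row-subset to the
#'   linked pairs.
#' @param stratum character vector per linked pair (`"public"`/`"private"`).
#' @return data frame, one row per criterion x stratum.
#' @export
validity_table <- function(ref_flags, claim_flags, stratum) {
  crit <- colnames(ref_flags)
  rows <- list()
  for (s in STRATA) {
    sel <- if (s == "total") rep(TRUE, length(stratum)) else stratum == s
    den <- sum(sel)
    for (cn in crit) {
      rf <- ref_flags[sel, cn]
      tot <- claim_flags$TOTAL[sel, cn]
      n_icd <- sum(claim_flags$ICD[sel, cn] | claim_flags$ICU_DAYS[sel, cn])
      n_rea <- sum(claim_flags$PROC_REA[sel, cn])
      n_act <- sum(claim_flags$PROF_ACT[sel, cn])
      n_tot <- sum(tot)
      sens <- spec <- lr_pos <- lr_neg <- NA_real_
      band_pos <- band_neg <- NA_character_
      if (any(rf) && any(!rf)) {
        v <- validity(confusion(rf, tot))
        sens <- v$sens; spec <- v$spec
        lr_pos <- v$lr_pos; lr_neg <- v$lr_neg
        band_pos <- v$band_pos; band_neg <- v$band_neg
      } else if (any(!rf)) {
        spec <- sum(!rf & !tot) / sum(!rf)
      } else if (any(rf)) {
        sens <- sum(rf & tot) / sum(rf)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        criterion = cn, stratum = s, n_linked = den,
        n_ref_pos = sum(rf), ref_pct = pct1(sum(rf), den),
        n_icd = n_icd, icd_pct = pct1(n_icd, den),
        n_proc_rea = n_rea, proc_rea_pct = pct1(n_rea, den),
        n_prof_act = n_act, prof_act_pct = pct1(n_act, den),
        n_total = n_tot, total_pct = pct1(n_tot, den),
        sens_pct = round_half_away(100 * sens, 1),
        spec_pct = round_half_away(100 * spec, 1),
        lr_neg = lr_neg, lr_pos = lr_pos,
        band_neg = band_neg, band_pos = band_pos,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Render the validity table for humans
#'
#' @param vt data frame from [validity_table()].
#' @return character data frame with em-dash sentinels and print-precision
#'   likelihood ratios (positive LR one decimal, negative LR two decimals).
#' @export
format_validity_table <- function(vt) {
  dash <- function(x, digits = 1) {
    ifelse(is.na(x), "–",
           formatC(round_half_away(x, digits), format = "f", digits = digits))
  }
  data.frame(
    criterion = vt$criterion,
    stratum = vt$stratum,
    ref = sprintf("%d (%s)", vt$n_ref_pos, dash(vt$ref_pct)),
    icd = sprintf("%d (%s)", vt$n_icd, dash(vt$icd_pct)),
    proc_rea = sprintf("%d (%s)", vt$n_proc_rea, dash(vt$proc_rea_pct)),
    prof_act = sprintf("%d (%s)", vt$n_prof_act, dash(vt$prof_act_pct)),
    total = sprintf("%d (%s)", vt$n_total, dash(vt$total_pct)),
    sens = dash(vt$sens_pct), spec = dash(vt$spec_pct),
    lr_neg = vapply(vt$lr_neg, format_lr_neg, ""),
    lr_pos = vapply(vt$lr_pos, format_lr_pos, ""),
    band_neg = ifelse(is.na(vt$band_neg), "–", vt$band_neg),
    band_pos = ifelse(is.na(vt$band_pos), "–", vt$band_pos),
    stringsAsFactors = FALSE
  )
}
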