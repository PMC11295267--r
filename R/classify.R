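# Stage-3 obstetric selection and the episode-level variable definitions:
# reason for hospitalization (first AIH), discharge type (last AIH), and the
# eleven severe-morbidity criteria flagged once per episode with their
# evidence channel (diagnosis fields, primary procedure, professional act,
# ICU stay-days variable).

FLAG_CHANNELS <- c("ICD", "PROC_REA", "PROF_ACT", "ICU_DAYS", "TOTAL")

# per-episode any() over a per-AIH logical, ep_i = episode index per AIH row
agg_any <- function(x, ep_i, n_ep) {
  out <- rep(FALSE, n_ep)
  hit <- unique(ep_i[x])
  out[hit] <- TRUE
  out
}

#' Classify the reason for hospitalization
#'
#' Applied to the first AIH of an (obstetric) episode. Specific rules are
#' evaluated for the four categories first — abortion by primary diagnosis;
#' delivery by primary diagnosis or a delivery procedure; pregnancy
#' complication and puerperium complication by primary diagnosis or their
#' marker procedures — and only then the residual rule: any other recorded
#' diagnosis counts as a pregnancy complication provided the procedure
#' performed is not a delivery procedure. A delivery procedure therefore
#' overrides a complication diagnosis, but never an abortive-outcome primary
#' diagnosis.
#'
#' @param primary_icd normalized primary diagnosis (vector, `NA` allowed).
#' @param procedure normalized primary procedure (vector, `NA` allowed).
#' @param has_other_icd logical vector: some diagnosis is recorded in any
#'   field of the first AIH.
#' @param rb a `rulebook`.
#' @return character vector over
#'   `c("delivery", "abortion", "pregnancy_complication",
#'   "puerperium_complication", "other", "missing")`.
#' @export
classify_reason <- function(primary_icd, procedure, has_other_icd = FALSE,
                            rb = default_rulebook()) {
  rr <- rb$reason_rules
  n <- length(primary_icd)
  has_other_icd <- rep_len(has_other_icd, n)
  in_proc <- function(set) !is.na(procedure) & procedure %in% set

  out <- rep(NA_character_, n)
  hit <- function(cond, label) out[is.na(out) & cond] <<- label
  hit(match_codes(primary_icd, rr$abortion$primary_icd), "abortion")
  hit(match_codes(primary_icd, rr$delivery$primary_icd) |
        in_proc(rr$delivery$procedures), "delivery")
  hit(match_codes(primary_icd, rr$pregnancy_complication$primary_icd) |
        in_proc(rr$pregnancy_complication$procedures),
      "pregnancy_complication")
  hit(match_codes(primary_icd, rr$puerperium_complication$primary_icd) |
        in_proc(rr$puerperium_complication$procedures),
      "puerperium_complication")
  if (isTRUE(rr$pregnancy_complication$any_other_icd)) {
    hit((!is.na(primary_icd) | has_other_icd) &
          !in_proc(rr$delivery$procedures), "pregnancy_complication")
  }
  hit(is.na(primary_icd) & is.na(procedure) & !has_other_icd, "missing")
  out[is.na(out)] <- "other"
  out
}

#' Classify the discharge type
#'
#' Maps the billing-reason token of the last AIH of the episode. The
#' continuing-stay token on the *last* AIH means no subsequent AIH was
#' found, so the episode is classified as a continuing inpatient stay.
#'
#' @param billing_reason character vector of billing-reason tokens (`""` for
#'   blank).
#' @param rb a `rulebook`.
#' @return character vector over `c("routine", "administrative",
#'   "continuing_stay", "death", "transfer", "blank")`.
#' @export
classify_discharge <- function(billing_reason, rb = default_rulebook()) {
  tok <- as.character(billing_reason)
  tok[is.na(tok)] <- ""
  unknown <- setdiff(unique(tok), names(rb$discharge_map))
  if (length(unknown)) {
    stop("unknown billing-reason token(s): ",
         paste(shQuote(unknown), collapse = ", "))
  }
  # index by position: subscripting a named vector with "" never matches
  unname(rb$discharge_map[match(tok, names(rb$discharge_map))])
}

#' Classify built episodes
#'
#' Runs obstetric identification, reason and discharge classification, and
#' the eleven criterion flags over all episodes at once, recording the
#' evidence channel of every flag (`ICD` = any configured diagnosis field on
#' any AIH of the episode; `PROC_REA` = primary procedure of any AIH;
#' `PROF_ACT` = any professional act joined by AIH number; `ICU_DAYS` = the
#' ICU stay-days variable, ICU criterion only). Multiple matches within an
#' episode count once.
#'
#' @param records stage-1-filtered AIH rows.
#' @param built result of [build_episodes()] on `records`.
#' @param acts data frame of professional acts (`aih_number`, `procedure`),
#'   already normalized; acts for unknown AIHs are ignored.
#' @param rb a `rulebook`.
#' @param use_acts_for_obstetric also accept professional acts as evidence of
#'   obstetric hospitalization (default `FALSE`: the acts table is joined
#'   after obstetric selection, so only the reduced table's fields decide).
#' @return list with `classification` (one row per episode: `episode_id`,
#'   `is_obstetric`, `reason` — `NA` for non-obstetric episodes —,
#'   `discharge`) and `flags` (list of logical episode-by-criterion matrices,
#'   one per evidence channel plus `TOTAL`).
#' @export
classify_episodes <- function(records, built, acts = NULL,
                              rb = default_rulebook(),
                              use_acts_for_obstetric = FALSE) {
  episodes <- built$episodes
  xwalk <- built$crosswalk
  n_ep <- nrow(episodes)
  rec <- records[match(xwalk$aih_number, records$aih_number), , drop = FALSE]
  ep_i <- match(xwalk$episode_id, episodes$episode_id)

  fields <- intersect(rb$diagnosis_fields, names(rec))
  if (!length(fields)) stop("none of the rulebook diagnosis fields are present")

  # obstetric identification
  obst_icd_aih <- rep(FALSE, nrow(rec))
  for (f in fields) {
    obst_icd_aih <- obst_icd_aih | match_codes(rec[[f]], rb$obstetric$icd)
  }
  obst_proc_aih <- !is.na(rec$primary_procedure) &
    rec$primary_procedure %in% rb$obstetric$procedures
  is_obst <- agg_any(obst_icd_aih | obst_proc_aih, ep_i, n_ep)

  # professional acts mapped to episodes
  if (is.null(acts)) {
    acts <- data.frame(aih_number = character(), procedure = character())
  }
  act_ep <- ep_i[match(acts$aih_number, xwalk$aih_number)]
  act_keep <- !is.na(act_ep)
  act_ep <- act_ep[act_keep]
  act_proc <- acts$procedure[act_keep]
  if (use_acts_for_obstetric) {
    is_obst <- is_obst |
      agg_any(act_proc %in% rb$obstetric$procedures, act_ep, n_ep)
  }

  # reason: first AIH of the episode
  first_rec <- records[match(episodes$first_aih, records$aih_number), ,
                       drop = FALSE]
  other_icd <- rep(FALSE, n_ep)
  for (f in fields) other_icd <- other_icd | !is.na(first_rec[[f]])
  reason <- classify_reason(first_rec$diag_primary,
                            first_rec$primary_procedure,
                            has_other_icd = other_icd, rb = rb)
  reason[!is_obst] <- NA_character_

  # discharge: last AIH of the episode
  last_rec <- records[match(episodes$last_aih, records$aih_number), ,
                      drop = FALSE]
  discharge <- classify_discharge(last_rec$billing_reason, rb)

  # criterion flags by evidence channel
  crit <- names(rb$criteria)
  mk <- function() matrix(FALSE, n_ep, length(crit),
                          dimnames = list(episodes$episode_id, crit))
  flags <- list(ICD = mk(), PROC_REA = mk(), PROF_ACT = mk(),
                ICU_DAYS = mk(), TOTAL = mk())
  icu_aih <- !is.na(rec$icu_days) & rec$icu_days > 0L
  for (cn in crit) {
    cr <- rb$criteria[[cn]]
    if (length(cr$icd$exact)) {
      m <- rep(FALSE, nrow(rec))
      for (f in fields) m <- m | match_codes(rec[[f]], cr$icd)
      flags$ICD[, cn] <- agg_any(m, ep_i, n_ep)
    }
    if (length(cr$procedures)) {
      flags$PROC_REA[, cn] <- agg_any(
        !is.na(rec$primary_procedure) &
          rec$primary_procedure %in% cr$procedures, ep_i, n_ep)
      if (length(act_proc)) {
        flags$PROF_ACT[, cn] <- agg_any(act_proc %in% cr$procedures,
                                        act_ep, n_ep)
      }
    }
    if (cr$uses_icu_days) {
      flags$ICU_DAYS[, cn] <- agg_any(icu_aih, ep_i, n_ep)
    }
    flags$TOTAL[, cn] <- flags$ICD[, cn] | flags$PROC_REA[, cn] |
      flags$PROF_ACT[, cn] | flags$ICU_DAYS[, cn]
  }

  classification <- data.frame(
    episode_id = episodes$episode_id,
    is_obstetric = is_obst,
    reason = reason,
    discharge = discharge,
    stringsAsFactors = FALSE
  )
  list(classification = classification, flags = flags)
}

#' Is an episode obstetric?
#'
#' Convenience wrapper over [classify_episodes()] for a single episode:
#' `TRUE` iff any AIH of the episode carries a chapter-O diagnosis in any
#' configured field or an obstetric primary procedure, regardless of the
#' AIH's position in the episode.
#'
#' @param episode_records the AIH rows of one episode.
#' @param rb a `rulebook`.
#' @return logical scalar.
#' @export
is_obstetric_episode <- function(episode_records, rb = default_rulebook()) {
  fields <- intersect(rb$diagnosis_fields, names(episode_records))
  icd <- FALSE
  for (f in fields) {
    icd <- icd || any(match_codes(episode_records[[f]], rb$obstetric$icd))
  }
  icd || any(!is.na(episode_records$primary_procedure) &
               episode_records$primary_procedure %in% rb$obstetric$procedures)
}
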