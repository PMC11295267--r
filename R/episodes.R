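# Episode-of-care construction: one hospital stay may be billed as several
# chained AIHs. An AIH closed with the "continuing inpatient stay" billing
# reason is followed by a new AIH at the same facility for the same woman
# (same CNES, same date of birth) admitted at most one day after the
# previous discharge.

#' Chaining predicate for consecutive AIHs of one episode
#'
#' @param prev,nxt single AIH rows (lists or one-row data frames) sharing
#'   facility code and date of birth.
#' @param continuing_token billing-reason token meaning "continuing
#'   inpatient stay".
#' @param max_gap_days maximum allowed gap (days) between the previous
#'   discharge and the next admission.
#' @return `TRUE` iff `nxt` continues the stay billed by `prev`.
#' @export
chain_predicate <- function(prev, nxt,
                            continuing_token = CONTINUING_STAY_TOKEN,
                            max_gap_days = 1L) {
  if (is.na(prev$billing_reason) || prev$billing_reason != continuing_token) {
    return(FALSE)
  }
  if (is.na(prev$discharge_date) || is.na(nxt$admission_date)) return(FALSE)
  gap <- as.numeric(nxt$admission_date - prev$discharge_date)
  gap >= 0 && gap <= max_gap_days
}

# greedy chronological chaining within one person-key group; rows is a
# data.frame already sorted by (admission_date, aih_number).
chain_group <- function(rows, continuing_token, max_gap_days) {
  n <- nrow(rows)
  assigned <- rep(FALSE, n)
  chains <- list()
  neg_gap <- 0L
  repeat {
    open <- which(!assigned)
    if (!length(open)) break
    head_i <- open[1L]            # earliest admission, then smallest number
    chain <- head_i
    assigned[head_i] <- TRUE
    unresolved <- FALSE
    repeat {
      tail_i <- chain[length(chain)]
      if (is.na(rows$billing_reason[tail_i]) ||
          rows$billing_reason[tail_i] != continuing_token) break
      if (is.na(rows$discharge_date[tail_i])) { unresolved <- TRUE; break }
      cand <- which(!assigned & !is.na(rows$admission_date))
      if (length(cand)) {
        gap <- as.numeric(rows$admission_date[cand] -
                            rows$discharge_date[tail_i])
        neg_gap <- neg_gap + sum(gap < 0)
        cand <- cand[gap >= 0 & gap <= max_gap_days]
      }
      if (!length(cand)) { unresolved <- TRUE; break }
      # earliest admission, tie-break smallest AIH number (sort order)
      nxt <- cand[1L]
      chain <- c(chain, nxt)
      assigned[nxt] <- TRUE
    }
    chains[[length(chains) + 1L]] <- list(idx = chain, unresolved = unresolved)
  }
  list(chains = chains, neg_gap = neg_gap)
}

#' Assemble AIH records into episodes of care
#'
#' Partitions the stage-1-filtered AIH rows into episodes by transitively
#' chaining "continuing inpatient stay" discharges within a person key
#' (facility code, date of birth). Chaining is greedy-chronological: each
#' continuing AIH is followed by the not-yet-assigned AIH with the earliest
#' admission date within the allowed gap, ties broken by smallest AIH
#' number, and each AIH succeeds at most one predecessor. The result does
#' not depend on input row order.
#'
#' Records with a missing date of birth cannot be attributed to a person key
#' and become singleton episodes.
#'
#' @param records data frame of AIH rows (needs `aih_number`, `cnes`, `dob`,
#'   `admission_date`, `discharge_date`, `billing_reason`).
#' @inheritParams chain_predicate
#' @return list with `episodes` (one row per episode: `episode_id`, `cnes`,
#'   `dob`, `admission_date` of the first AIH, `discharge_date` of the last,
#'   `n_aihs`, `unresolved_continuation`) and `crosswalk` (`aih_number`,
#'   `episode_id`, `position`).
#' @export
build_episodes <- function(records,
                           continuing_token = CONTINUING_STAY_TOKEN,
                           max_gap_days = 1L) {
  ord <- order(records$cnes, records$dob, records$admission_date,
               records$aih_number, method = "radix")
  rec <- records[ord, , drop = FALSE]
  key <- paste(rec$cnes, rec$dob, sep = "\r")
  key[is.na(rec$dob)] <- paste0("\r#nodob#", seq_len(nrow(rec))[is.na(rec$dob)])

  # fast path: person keys with one AIH, or no continuing token at all,
  # yield singleton episodes without running the chain search
  grp <- split(seq_len(nrow(rec)), factor(key, levels = unique(key)))
  neg_gap <- 0L
  ep_rows <- vector("list", length(grp))
  for (g in seq_along(grp)) {
    idx <- grp[[g]]
    simple <- length(idx) == 1L ||
      !any(rec$billing_reason[idx] == continuing_token, na.rm = TRUE)
    if (simple) {
      ep_rows[[g]] <- lapply(idx, function(i) {
        list(idx = i,
             unresolved = !is.na(rec$billing_reason[i]) &&
               rec$billing_reason[i] == continuing_token)
      })
    } else {
      res <- chain_group(rec[idx, , drop = FALSE], continuing_token,
                         max_gap_days)
      neg_gap <- neg_gap + res$neg_gap
      ep_rows[[g]] <- lapply(res$chains, function(ch) {
        list(idx = idx[ch$idx], unresolved = ch$unresolved)
      })
    }
  }
  eps <- unlist(ep_rows, recursive = FALSE)
  if (neg_gap > 0L) {
    warning(neg_gap, " continuing-stay candidate pair(s) with a negative ",
            "discharge-to-admission gap were not chained")
  }

  n_ep <- length(eps)
  id_fmt <- paste0("E%0", max(6L, nchar(n_ep)), "d")
  episode_id <- sprintf(id_fmt, seq_len(n_ep))
  first_i <- vapply(eps, function(e) e$idx[1L], 1L)
  last_i <- vapply(eps, function(e) e$idx[length(e$idx)], 1L)
  episodes <- data.frame(
    episode_id = episode_id,
    cnes = rec$cnes[first_i],
    dob = rec$dob[first_i],
    admission_date = rec$admission_date[first_i],
    discharge_date = rec$discharge_date[last_i],
    n_aihs = vapply(eps, function(e) length(e$idx), 1L),
    unresolved_continuation = vapply(eps, function(e) e$unresolved, TRUE),
    first_aih = rec$aih_number[first_i],
    last_aih = rec$aih_number[last_i],
    stringsAsFactors = FALSE
  )
  crosswalk <- data.frame(
    aih_number = rec$aih_number[unlist(lapply(eps, `[[`, "idx"))],
    episode_id = rep(episode_id, episodes$n_aihs),
    position = unlist(lapply(episodes$n_aihs, seq_len)),
    stringsAsFactors = FALSE
  )
  list(episodes = episodes, crosswalk = crosswalk)
}

#' Episode flow counts
#'
#' @param episodes the `episodes` data frame from [build_episodes()].
#' @return named list: total episodes, total AIHs, multi-AIH episodes,
#'   unresolved continuing-stay episodes.
#' @export
episode_summary <- function(episodes) {
  list(
    episodes = nrow(episodes),
    aihs = sum(episodes$n_aihs),
    multi_aih = sum(episodes$n_aihs > 1L),
    unresolved_continuation = sum(episodes$unresolved_continuation)
  )
}
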