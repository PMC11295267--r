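# Deterministic multi-pass record linkage between claims episodes and
# reference-standard hospitalizations on six keys: facility code, date of
# birth, admission date, discharge date, race/skin colour, residence
# postcode. Matching is exact within a pass; later passes relax keys for the
# records still unmatched. A missing key value never satisfies equality, and
# a key block with more than one candidate on either side is conservative:
# nobody in it is matched in that pass.

LINK_KEYS <- c("cnes", "dob", "admission_date", "discharge_date",
               "race_color", "postcode")

#' Default linkage pass specification
#'
#' Four passes: (1) all six keys; (2) without postcode; (3) without postcode
#' and race/colour; (4) without postcode and race/colour, allowing the
#' discharge date to differ by up to one day (split billing can shift the
#' recorded discharge).
#'
#' @return list of passes, each with `exact` (key names compared exactly)
#'   and `discharge_tol` (days).
#' @export
default_link_passes <- function() {
  list(
    list(exact = LINK_KEYS, discharge_tol = 0L),
    list(exact = setdiff(LINK_KEYS, "postcode"), discharge_tol = 0L),
    list(exact = setdiff(LINK_KEYS, c("postcode", "race_color")),
         discharge_tol = 0L),
    list(exact = c("cnes", "dob", "admission_date"), discharge_tol = 1L)
  )
}

key_string <- function(df, keys) {
  vals <- lapply(keys, function(k) as.character(df[[k]]))
  any_na <- Reduce(`|`, lapply(vals, is.na))
  out <- do.call(paste, c(vals, sep = "\r"))
  out[any_na] <- NA_character_
  out
}

#' Deterministically link episodes to reference hospitalizations
#'
#' @param episodes data frame with an `id` column and the six key columns
#'   (`cnes`, `dob`, `admission_date`, `discharge_date`, `race_color`,
#'   `postcode`).
#' @param reference data frame with the same key columns and an `id` column;
#'   ids must be unique.
#' @param passes pass specification, see [default_link_passes()].
#' @return list of class `link_result`: `pairs` (`episode_id`,
#'   `reference_id`, `pass`), `unmatched_episodes`, `unmatched_reference`
#'   (id vectors) and `ambiguity_count` (key blocks skipped because either
#'   side had several candidates).
#' @export
deterministic_link <- function(episodes, reference,
                               passes = default_link_passes()) {
  if (anyDuplicated(reference$id)) stop("duplicate reference ids")
  if (anyDuplicated(episodes$id)) stop("duplicate episode ids")

  e_free <- rep(TRUE, nrow(episodes))
  r_free <- rep(TRUE, nrow(reference))
  pairs <- list()
  ambiguity <- 0L

  for (p in seq_along(passes)) {
    spec <- passes[[p]]
    tol <- if (is.null(spec$discharge_tol)) 0L else spec$discharge_tol
    ek <- key_string(episodes, spec$exact)
    rk <- key_string(reference, spec$exact)
    ei <- which(e_free & !is.na(ek))
    ri <- which(r_free & !is.na(rk))
    if (!length(ei) || !length(ri)) next
    common <- intersect(ek[ei], rk[ri])
    if (!length(common)) next
    e_by <- split(ei, factor(ek[ei], levels = common))
    r_by <- split(ri, factor(rk[ri], levels = common))
    for (b in seq_along(common)) {
      es <- e_by[[b]]; rs <- r_by[[b]]
      if (length(es) == 1L && length(rs) == 1L) {
        if (tol > 0L) {
          de <- episodes$discharge_date[es]
          dr <- reference$discharge_date[rs]
          if (is.na(de) || is.na(dr) || abs(as.numeric(de - dr)) > tol) next
        }
        pairs[[length(pairs) + 1L]] <-
          data.frame(episode_id = episodes$id[es],
                     reference_id = reference$id[rs],
                     pass = p, stringsAsFactors = FALSE)
        e_free[es] <- FALSE
        r_free[rs] <- FALSE
      } else {
        ambiguity <- ambiguity + 1L
      }
    }
  }

  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(episode_id = character(), reference_id = character(),
               pass = integer(), stringsAsFactors = FALSE)
  structure(list(
    pairs = pairs,
    unmatched_episodes = episodes$id[e_free],
    unmatched_reference = reference$id[r_free],
    ambiguity_count = ambiguity
  ), class = "link_result")
}

#' Linkage flow summary
#'
#' @param result a `link_result`.
#' @return list with per-pass match counts and match rates on each side.
#' @export
link_report <- function(result) {
  stopifnot(inherits(result, "link_result"))
  n_pairs <- nrow(result$pairs)
  n_ep <- n_pairs + length(result$unmatched_episodes)
  n_ref <- n_pairs + length(result$unmatched_reference)
  list(
    matched = n_pairs,
    by_pass = table(factor(result$pairs$pass)),
    episode_match_rate = if (n_ep > 0) n_pairs / n_ep else NA_real_,
    reference_match_rate = if (n_ref > 0) n_pairs / n_ref else NA_real_,
    ambiguity_count = result$ambiguity_count
  )
}
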