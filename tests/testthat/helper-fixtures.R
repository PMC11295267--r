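# Build a minimal AIH row set in the canonical reduced layout.
aih_rows <- function(aih_number, cnes = "1000001", dob = as.Date("1990-01-01"),
                     admission, discharge, billing_reason = "1",
                     aih_type = 1L, sex = "F", age_years = NA_integer_,
                     race_color = "1", postcode = "01000000",
                     primary_procedure = NA_character_, icu_days = 0L,
                     diag_primary = NA_character_, ...) {
  n <- length(aih_number)
  df <- data.frame(
    aih_number = aih_number,
    cnes = rep_len(cnes, n),
    aih_type = rep_len(aih_type, n),
    dob = rep_len(as.Date(dob), n),
    age_years = rep_len(age_years, n),
    sex = rep_len(sex, n),
    race_color = rep_len(race_color, n),
    postcode = rep_len(postcode, n),
    admission_date = as.Date(admission),
    discharge_date = as.Date(discharge),
    billing_reason = rep_len(billing_reason, n),
    primary_procedure = rep_len(primary_procedure, n),
    icu_days = rep_len(icu_days, n),
    stringsAsFactors = FALSE
  )
  diag_fields <- c("diag_primary", "diag_secondary",
                   paste0("diag_secondary", 1:9),
                   "diag_associated", "diag_notification", "diag_death")
  for (f in diag_fields) df[[f]] <- NA_character_
  df$diag_primary <- rep_len(diag_primary, n)
  extra <- list(...)
  for (f in names(extra)) df[[f]] <- rep_len(extra[[f]], n)
  df$source_row <- seq_len(n)
  df
}

# Independent oracle for episode chaining within one person-key group:
# enumerate every order-respecting partition of the rows into chains whose
# consecutive pairs satisfy chain_predicate(). Each partition is a set of
# chains; each chain a character vector of AIH numbers.
enumerate_chain_partitions <- function(rows) {
  n <- nrow(rows)
  ord <- order(rows$admission_date, rows$aih_number)
  rows <- rows[ord, , drop = FALSE]
  results <- list()
  recurse <- function(i, chains) {
    if (i > n) {
      results[[length(results) + 1L]] <<- chains
      return(invisible())
    }
    nxt <- rows[i, , drop = FALSE]
    # append to any chain whose tail can be continued by row i
    for (ci in seq_along(chains)) {
      tail_i <- chains[[ci]][length(chains[[ci]])]
      prev <- rows[rows$aih_number == tail_i, , drop = FALSE]
      if (chain_predicate(prev, nxt)) {
        chains2 <- chains
        chains2[[ci]] <- c(chains2[[ci]], nxt$aih_number)
        recurse(i + 1L, chains2)
      }
    }
    # or start a new chain
    recurse(i + 1L, c(chains, list(nxt$aih_number)))
  }
  recurse(1L, list())
  results
}

# Independent reference implementation of the documented chaining rule,
# written as plainly as possible: repeatedly take the earliest unassigned
# AIH (admission date, then AIH number) as a chain head, then extend the
# chain maximally, each step taking the earliest eligible unassigned AIH.
greedy_reference_chains <- function(rows, max_gap_days = 1L) {
  ord <- order(rows$admission_date, rows$aih_number)
  rows <- rows[ord, , drop = FALSE]
  unassigned <- seq_len(nrow(rows))
  chains <- list()
  while (length(unassigned)) {
    chain <- unassigned[1]
    unassigned <- unassigned[-1]
    repeat {
      tail_row <- rows[chain[length(chain)], , drop = FALSE]
      nxt <- NA
      for (i in unassigned) {
        if (chain_predicate(tail_row, rows[i, , drop = FALSE],
                            max_gap_days = max_gap_days)) {
          nxt <- i
          break
        }
      }
      if (is.na(nxt)) break
      chain <- c(chain, nxt)
      unassigned <- setdiff(unassigned, nxt)
    }
    chains[[length(chains) + 1]] <- rows$aih_number[chain]
  }
  chains
}

canonical_partition <- function(chains) {
  s <- sort(vapply(chains, paste, "", collapse = ">"))
  paste(s, collapse = "|")
}

# chains actually built by the package for one person-key group
built_partition <- function(rows) {
  built <- suppressWarnings(build_episodes(rows))
  unname(split(built$crosswalk$aih_number, built$crosswalk$episode_id))
}

zero_noise_config <- function(seed, n_public = 5, n_private = 5,
                              episodes = 60, ...) {
  sim_config(
    seed = seed,
    n_hospitals_public = n_public, n_hospitals_private = n_private,
    episodes_per_hospital = episodes,
    record_sens = 1, record_false_pos = 0,
    p_undercapture = c(public = 0, private = 0),
    p_overcapture = c(public = 0, private = 0),
    p_key_missing = c(postcode = 0, race_color = 0),
    p_key_corrupt = c(dob = 0, admission_date = 0, discharge_date = 0,
                      postcode = 0, race_color = 0),
    ...
  )
}
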