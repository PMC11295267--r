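# Synthetic claims generator with known ground truth. Emulates the study
# conditions of a 30-day obstetric hospitalization census across public and
# private hospitals paired with the AIH billing records those stays would
# produce: per-condition recording sensitivity and false-positive rates by
# hospital type, under-/over-capture of whole admissions, episode splitting
# via the continuing-inpatient-stay billing reason, and linkage-key
# missingness/corruption.

#' Simulation configuration
#'
#' Defaults are the study conditions the generator emulates: 50 public and
#' 28 private hospitals observed for a 30-day census window, 430 stays per
#' hospital, reason and discharge mixes and per-condition prevalences taken
#' from a national obstetric census, recording sensitivity / false-positive
#' rates by hospital type from observed claims-recording behaviour,
#' 14.5% under-capture in private hospitals and 0.2% over-capture in public
#' hospitals.
#'
#' @param seed integer seed fixing the full output.
#' @param n_hospitals_public,n_hospitals_private hospital counts.
#' @param episodes_per_hospital reference stays per hospital.
#' @param condition_prevalence named numeric over the 11 criteria:
#'   per-stay probability of truly having the condition.
#' @param record_sens,record_false_pos either a single number applied to
#'   every criterion and hospital type, or an 11 x 2 matrix
#'   (criteria x `public`,`private`): probability that a true condition is
#'   coded / that a false code appears.
#' @param record_sens2 probability of evidence in a second, independent
#'   channel given a true condition (same shapes; default 0).
#' @param p_undercapture,p_overcapture named over `public`,`private`:
#'   probability a reference stay produced no AIH at all / expected spurious
#'   AIH-only stays per reference stay.
#' @param p_split probability a captured stay is billed as two chained AIHs.
#' @param p_key_missing named probabilities of a missing claims-side
#'   `postcode` / `race_color`.
#' @param p_key_corrupt named probabilities of corrupting claims-side keys
#'   (`dob`, `admission_date`, `discharge_date` shifted by a day;
#'   `postcode`, `race_color` replaced).
#' @param reason_mix,discharge_mix category distributions of the reference
#'   stays (must sum to 1).
#' @param p_ref_reason_missing probability the reference reason is missing.
#' @param n_stage1_noise,n_nonobstetric extra AIH rows per hospital that the
#'   stage-1 filter / the obstetric selection must reject.
#' @param window_start first day of the census window.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_hospitals_public = 50L,
                       n_hospitals_private = 28L,
                       episodes_per_hospital = 430L,
                       condition_prevalence = NULL,
                       record_sens = NULL,
                       record_false_pos = NULL,
                       record_sens2 = 0,
                       p_undercapture = c(public = 0, private = 0.145),
                       p_overcapture = c(public = 0.002, private = 0),
                       p_split = 0.03,
                       p_key_missing = c(postcode = 0.05, race_color = 0.05),
                       p_key_corrupt = c(dob = 0, admission_date = 0,
                                         discharge_date = 0, postcode = 0,
                                         race_color = 0),
                       reason_mix = c(delivery = 0.725, abortion = 0.088,
                                      pregnancy_complication = 0.165,
                                      puerperium_complication = 0.022),
                       discharge_mix = c(routine = 0.971,
                                         administrative = 0.013,
                                         death = 0.001, transfer = 0.015),
                       p_ref_reason_missing = 0,
                       n_stage1_noise = 5L,
                       n_nonobstetric = 10L,
                       window_start = as.Date("2021-11-01")) {
  types <- c("public", "private")
  crit_mat <- function(x, default) {
    if (is.null(x)) x <- default
    if (is.matrix(x)) {
      stopifnot(nrow(x) == length(CRITERIA), ncol(x) == 2)
      rownames(x) <- CRITERIA; colnames(x) <- types
      return(x)
    }
    matrix(rep_len(as.numeric(x), 1), length(CRITERIA), 2,
           dimnames = list(CRITERIA, types))
  }
  default_sens <- cbind(
    public  = c(0.393, 0.202, 0, 0.426, 0.052, 0.043, 0.935, 0.375, 0.161,
                0.460, 0.650),
    private = c(0.337, 0.313, 0, 0.255, 0.029, 0.100, 0.902, 0.348, 0.114,
                0.616, 0.860)
  )
  default_fp <- cbind(
    public  = c(0.023, 0.015, 0, 0.001, 0.010, 0.000, 0.000, 0.000, 0.000,
                0.023, 0.003),
    private = c(0.036, 0.004, 0, 0.004, 0.017, 0.001, 0.000, 0.000, 0.001,
                0.032, 0.006)
  )
  rownames(default_sens) <- rownames(default_fp) <- CRITERIA
  if (is.null(condition_prevalence)) {
    condition_prevalence <- c(
      severe_preeclampsia = 0.0281, eclampsia = 0.0043, hellp = 0.0050,
      abruptio_placentae = 0.0060, hemorrhage = 0.0219,
      uterine_rupture = 0.0008, ectopic_pregnancy = 0.0072,
      hysterectomy = 0.0022, laparotomy = 0.0072, transfusion = 0.0089,
      icu = 0.0112
    )
  }
  if (is.numeric(condition_prevalence) && is.null(names(condition_prevalence)) &&
      length(condition_prevalence) == 1) {
    condition_prevalence <- stats::setNames(
      rep(condition_prevalence, length(CRITERIA)), CRITERIA)
  }
  stopifnot(setequal(names(condition_prevalence), CRITERIA))
  condition_prevalence <- condition_prevalence[CRITERIA]

  cfg <- list(
    seed = as.integer(seed),
    n_hospitals_public = as.integer(n_hospitals_public),
    n_hospitals_private = as.integer(n_hospitals_private),
    episodes_per_hospital = as.integer(episodes_per_hospital),
    condition_prevalence = condition_prevalence,
    record_sens = crit_mat(record_sens, default_sens),
    record_false_pos = crit_mat(record_false_pos, default_fp),
    record_sens2 = crit_mat(record_sens2, 0),
    p_undercapture = p_undercapture[types],
    p_overcapture = p_overcapture[types],
    p_split = p_split,
    p_key_missing = p_key_missing,
    p_key_corrupt = p_key_corrupt,
    reason_mix = reason_mix,
    discharge_mix = discharge_mix,
    p_ref_reason_missing = p_ref_reason_missing,
    n_stage1_noise = as.integer(n_stage1_noise),
    n_nonobstetric = as.integer(n_nonobstetric),
    window_start = as.Date(window_start)
  )
  probs <- c(cfg$condition_prevalence, cfg$record_sens, cfg$record_false_pos,
             cfg$record_sens2, cfg$p_undercapture, cfg$p_overcapture,
             cfg$p_split, unlist(cfg$p_key_missing),
             unlist(cfg$p_key_corrupt), cfg$p_ref_reason_missing)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("sim_config: all probabilities must be in [0, 1]")
  }
  if (abs(sum(cfg$reason_mix) - 1) > 1e-8 ||
      abs(sum(cfg$discharge_mix) - 1) > 1e-8) {
    stop("sim_config: reason_mix and discharge_mix must each sum to 1")
  }
  structure(cfg, class = "sim_config")
}

# evidence channel of each criterion (generator routing): diagnoses are
# coded as ICDs; transfusion and ICU only appear through the
# professional-acts table / the ICU stay-days variable; the two surgical
# procedures through professional acts.
SIM_CHANNEL <- c(
  severe_preeclampsia = "ICD", eclampsia = "ICD", hellp = "ICD",
  abruptio_placentae = "ICD", hemorrhage = "ICD", uterine_rupture = "ICD",
  ectopic_pregnancy = "ICD", hysterectomy = "PROF_ACT",
  laparotomy = "PROF_ACT", transfusion = "PROF_ACT", icu = "ICU_DAYS"
)
SIM_CHANNEL2 <- c(
  severe_preeclampsia = "ICD", eclampsia = "PROF_ACT", hellp = "ICD",
  abruptio_placentae = "ICD", hemorrhage = "ICD", uterine_rupture = "ICD",
  ectopic_pregnancy = "PROF_ACT", hysterectomy = "ICD",
  laparotomy = "PROF_ACT", transfusion = "PROF_ACT", icu = "PROF_ACT"
)

# primary-diagnosis / primary-procedure pools per reason; pools avoid every
# criterion ICD so condition evidence stays under the generator's control
SIM_REASON_ICD <- list(
  delivery = c("O800", "O809", "O620", "O680", "O751", "O839"),
  abortion = c("O020", "O034", "O039", "O049", "O059", "O069", "O079",
               "O089"),
  pregnancy_complication = c("O139", "O219", "O239", "O244", "O269", "O300",
                             "O410", "O470", "O489", "O200"),
  puerperium_complication = c("O860", "O868", "O900", "O913")
)
SIM_REASON_PROC <- list(
  delivery = c("0310010012", "0310010039", "0411010034", "0411010042"),
  abortion = "0411020013",
  pregnancy_complication = "0303100044",
  puerperium_complication = "0303100010"
)

sim_criterion_code <- function(criterion, channel, rb) {
  cr <- rb$criteria[[criterion]]
  if (channel == "ICD") cr$icd$exact else cr$procedures
}

#' Generate a synthetic reference census and paired claims tables
#'
#' @param config a [sim_config()].
#' @param rb a `rulebook` supplying the code sets used to encode evidence.
#' @return list with `reference` (one row per census hospitalization),
#'   `reduced` (one row per AIH, canonical layout, ready for
#'   [stage1_filter()]), `acts` (professional acts) and `truth` (ground
#'   truth: `pairing` of reference id to first AIH number, `flags` matrix of
#'   true conditions per reference stay, `hospitals`, and the analytic
#'   `expected` metrics from [expected_metrics()]).
#' @export
simulate_claims <- function(config = sim_config(), rb = default_rulebook()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  types <- c(rep("public", config$n_hospitals_public),
             rep("private", config$n_hospitals_private))
  H <- length(types)
  hospitals <- data.frame(
    cnes = sprintf("%07d", 1000000L + seq_len(H)),
    hospital_type = types, stringsAsFactors = FALSE
  )
  E <- config$episodes_per_hospital
  w0 <- config$window_start

  # reference stays + spurious claims-only stays, per hospital
  n_spur <- stats::rbinom(H, E, config$p_overcapture[types])
  n_stay <- E + n_spur
  hosp_i <- rep(seq_len(H), n_stay)
  N <- sum(n_stay)
  in_reference <- unlist(lapply(seq_len(H), function(h) {
    c(rep(TRUE, E), rep(FALSE, n_spur[h]))
  }))
  stay_type <- types[hosp_i]

  admission <- w0 + sample(0:29, N, replace = TRUE)
  los <- sample(1:4, N, replace = TRUE, prob = c(0.25, 0.35, 0.3, 0.1))
  discharge <- admission + los
  # dates of birth unique within a hospital: the person key is
  # (facility, dob), so uniqueness keeps ground-truth stays separable
  # (even day-offsets; decoy rows use odd offsets so they can never
  # interfere with episode chaining)
  dob_offset <- 2L * unlist(lapply(n_stay, function(n) sample(1827:9100, n)))
  dob <- w0 - dob_offset
  race <- sample(c("1", "2", "3", "4", "5"), N, replace = TRUE,
                 prob = c(0.40, 0.10, 0.44, 0.05, 0.01))
  postcode <- sprintf("%08d", sample.int(99999999L, N, replace = TRUE))
  reason <- sample(names(config$reason_mix), N, replace = TRUE,
                   prob = config$reason_mix)
  discharge_type <- sample(names(config$discharge_mix), N, replace = TRUE,
                           prob = config$discharge_mix)

  true_flags <- vapply(CRITERIA, function(cn) {
    stats::runif(N) < config$condition_prevalence[cn]
  }, logical(N))
  if (N == 1L) true_flags <- matrix(true_flags, 1,
                                    dimnames = list(NULL, CRITERIA))

  reference <- data.frame(
    id = sprintf("R%06d", seq_len(sum(in_reference))),
    cnes = hospitals$cnes[hosp_i[in_reference]],
    hospital_type = stay_type[in_reference],
    dob = dob[in_reference],
    admission_date = admission[in_reference],
    discharge_date = discharge[in_reference],
    race_color = race[in_reference],
    postcode = postcode[in_reference],
    reason = ifelse(stats::runif(sum(in_reference)) <
                      config$p_ref_reason_missing, "",
                    reason[in_reference]),
    discharge_type = discharge_type[in_reference],
    stringsAsFactors = FALSE
  )
  ref_flag_df <- as.data.frame(true_flags[in_reference, , drop = FALSE])
  names(ref_flag_df) <- paste0("flag_", CRITERIA)
  reference <- cbind(reference, ref_flag_df)

  # which stays produced AIHs at all
  captured <- rep(TRUE, N)
  captured[in_reference] <-
    stats::runif(sum(in_reference)) >= config$p_undercapture[stay_type[in_reference]]

  # ---- claims side ----
  ci <- which(captured)
  nc <- length(ci)
  split2 <- stats::runif(nc) < config$p_split & los[ci] >= 1L
  n_aih <- 1L + split2
  first_row <- cumsum(c(1L, n_aih))[seq_len(nc)]
  n_rows <- sum(n_aih)
  stay_of_row <- rep(ci, n_aih)
  is_second <- sequence(n_aih) == 2L

  mid <- admission[ci] + floor(los[ci] / 2)
  gap <- sample(0:1, nc, replace = TRUE)
  row_adm <- admission[stay_of_row]
  row_dis <- discharge[stay_of_row]
  srow <- rep(seq_len(nc), n_aih)          # claim-stay index per AIH row
  row_dis[!is_second & split2[srow]] <- mid[srow][!is_second & split2[srow]]
  row_adm[is_second] <- pmin(mid[srow] + gap[srow],
                             discharge[ci][srow])[is_second]

  final_token <- function(dt) {
    out <- character(length(dt))
    r <- dt == "routine"
    out[r] <- sample(c("1", "6.1", "6.2", "6.3", "6.4"), sum(r),
                     replace = TRUE, prob = c(0.8, 0.05, 0.05, 0.05, 0.05))
    out[dt == "administrative"] <- "5"
    d <- dt == "death"
    out[d] <- sample(c("4", "6.5", "6.6", "6.7"), sum(d), replace = TRUE)
    out[dt == "transfer"] <- "3"
    out
  }
  last_token <- final_token(discharge_type[ci])
  billing <- ifelse(!is_second & split2[srow], CONTINUING_STAY_TOKEN,
                    last_token[srow])

  reason_c <- reason[ci]
  prim_icd <- vapply(reason_c, function(r) sample(SIM_REASON_ICD[[r]], 1L),
                     "")
  prim_proc <- vapply(reason_c, function(r) sample(SIM_REASON_PROC[[r]], 1L),
                      "")

  # claims-side linkage keys, with missingness / corruption
  c_dob <- dob[ci]
  hit <- stats::runif(nc) < config$p_key_corrupt[["dob"]]
  c_dob[hit] <- c_dob[hit] + sample(c(-1L, 1L), sum(hit), replace = TRUE)
  c_race <- race[ci]
  hit <- stats::runif(nc) < config$p_key_corrupt[["race_color"]]
  c_race[hit] <- sample(c("1", "2", "3", "4", "5"), sum(hit), replace = TRUE)
  c_post <- postcode[ci]
  hit <- stats::runif(nc) < config$p_key_corrupt[["postcode"]]
  c_post[hit] <- sprintf("%08d", sample.int(99999999L, sum(hit), TRUE))
  c_race[stats::runif(nc) < config$p_key_missing[["race_color"]]] <- ""
  c_post[stats::runif(nc) < config$p_key_missing[["postcode"]]] <- ""
  adm_shift <- (stats::runif(nc) < config$p_key_corrupt[["admission_date"]]) *
    sample(c(-1L, 1L), nc, replace = TRUE)
  dis_shift <- (stats::runif(nc) < config$p_key_corrupt[["discharge_date"]]) *
    sample(c(-1L, 1L), nc, replace = TRUE)
  row_adm[!is_second] <- row_adm[!is_second] + adm_shift[srow][!is_second]
  row_dis[is_second | !split2[srow]] <-
    row_dis[is_second | !split2[srow]] + dis_shift[srow][is_second | !split2[srow]]

  aih_number <- sprintf("A%08d", seq_len(n_rows))
  age_years <- as.integer(floor(as.numeric(row_adm - c_dob[srow]) / 365.25))

  reduced <- data.frame(
    aih_number = aih_number,
    cnes = hospitals$cnes[hosp_i[stay_of_row]],
    aih_type = 1L,
    dob = c_dob[srow],
    age_years = age_years,
    sex = "F",
    race_color = c_race[srow],
    postcode = c_post[srow],
    admission_date = row_adm,
    discharge_date = row_dis,
    billing_reason = billing,
    primary_procedure = prim_proc[srow],
    icu_days = 0L,
    stringsAsFactors = FALSE
  )
  for (f in DEFAULT_DIAGNOSIS_FIELDS) reduced[[f]] <- NA_character_
  reduced$diag_primary <- prim_icd[srow]

  # professional acts: the primary procedure of each AIH is also an act
  acts_aih <- aih_number
  acts_proc <- prim_proc[srow]

  # condition evidence
  nonprimary <- setdiff(DEFAULT_DIAGNOSIS_FIELDS, "diag_primary")
  recorded <- matrix(FALSE, N, length(CRITERIA),
                     dimnames = list(NULL, CRITERIA))
  for (cn in CRITERIA) {
    p1 <- ifelse(true_flags[, cn], config$record_sens[cn, stay_type],
                 config$record_false_pos[cn, stay_type])
    rec1 <- stats::runif(N) < p1
    p2 <- ifelse(true_flags[, cn], config$record_sens2[cn, stay_type], 0)
    rec2 <- stats::runif(N) < p2
    recorded[, cn] <- rec1 | rec2

    for (pass in 1:2) {
      rec <- if (pass == 1) rec1 else rec2
      channel <- if (pass == 1) SIM_CHANNEL[[cn]] else SIM_CHANNEL2[[cn]]
      sidx <- which(rec & captured)           # stays, by stay index
      if (!length(sidx)) next
      k <- match(sidx, ci)                    # claim-stay index
      target_row <- first_row[k] +
        floor(stats::runif(length(k)) * n_aih[k])
      codes <- sim_criterion_code(cn, channel, rb)
      code <- codes[1L + floor(stats::runif(length(k)) * length(codes))]
      if (channel == "ICD") {
        # random secondary field, probing onward so codes recorded for
        # several conditions on one AIH never overwrite each other
        start <- 1L + floor(stats::runif(length(k)) * length(nonprimary))
        for (j in seq_along(k)) {
          for (off in seq_along(nonprimary) - 1L) {
            f <- nonprimary[1L + (start[j] + off - 1L) %% length(nonprimary)]
            if (is.na(reduced[[f]][target_row[j]])) {
              reduced[[f]][target_row[j]] <- code[j]
              break
            }
          }
        }
      } else if (channel == "PROF_ACT") {
        acts_aih <- c(acts_aih, aih_number[target_row])
        acts_proc <- c(acts_proc, code)
      } else if (channel == "ICU_DAYS") {
        reduced$icu_days[target_row] <- sample(1:10, length(k), replace = TRUE)
      }
    }
  }

  # decoy rows: must fall to the stage-1 filter / the obstetric selection
  decoys <- sim_decoy_rows(hospitals, hosp_i, config, w0)
  if (nrow(decoys)) {
    decoys$aih_number <- sprintf("A%08d", n_rows + seq_len(nrow(decoys)))
    reduced <- rbind(reduced, decoys[, names(reduced)])
  }

  acts <- data.frame(aih_number = acts_aih, procedure = acts_proc,
                     stringsAsFactors = FALSE)
  acts <- acts[order(acts$aih_number, acts$procedure), , drop = FALSE]
  rownames(acts) <- NULL

  pairing <- data.frame(
    reference_id = reference$id,
    first_aih = NA_character_,
    captured = captured[in_reference],
    stringsAsFactors = FALSE
  )
  cap_ref <- in_reference[ci]                 # captured stays in reference?
  ref_of_stay <- cumsum(in_reference)         # reference row per stay index
  pairing$first_aih[ref_of_stay[ci[cap_ref]]] <- aih_number[first_row[cap_ref]]

  list(
    reference = reference,
    reduced = reduced,
    acts = acts,
    truth = list(
      pairing = pairing,
      flags = true_flags[in_reference, , drop = FALSE],
      recorded = recorded[in_reference, , drop = FALSE],
      hospitals = hospitals,
      expected = expected_metrics(config)
    )
  )
}

# rows the pipeline must reject: non-type-1 / male / out-of-age AIHs and
# non-obstetric female admissions
sim_decoy_rows <- function(hospitals, hosp_i, config, w0) {
  H <- nrow(hospitals)
  n1 <- config$n_stage1_noise
  n2 <- config$n_nonobstetric
  n <- H * (n1 + n2)
  if (n == 0L) {
    return(data.frame())
  }
  hosp <- rep(seq_len(H), each = n1 + n2)
  kind <- rep(rep(c("stage1", "nonobst"), c(n1, n2)), H)
  adm <- w0 + sample(0:29, n, replace = TRUE)
  dis <- adm + sample(1:6, n, replace = TRUE)
  df <- data.frame(
    aih_number = NA_character_,
    cnes = hospitals$cnes[hosp],
    aih_type = 1L,
    dob = w0 - (2L * sample(3750:8000, n, replace = TRUE) + 1L),
    age_years = NA_integer_,
    sex = "F",
    race_color = sample(c("1", "3"), n, replace = TRUE),
    postcode = sprintf("%08d", sample.int(99999999L, n, replace = TRUE)),
    admission_date = adm,
    discharge_date = dis,
    billing_reason = "1",
    primary_procedure = "0303010019",
    icu_days = 0L,
    stringsAsFactors = FALSE
  )
  for (f in DEFAULT_DIAGNOSIS_FIELDS) df[[f]] <- NA_character_
  df$diag_primary <- sample(c("J128", "A090", "N390", "K359"),
                            n, replace = TRUE)
  s1 <- kind == "stage1"
  violation <- sample(c("type", "sex", "age"), sum(s1), replace = TRUE)
  df$aih_type[s1][violation == "type"] <- 5L
  df$sex[s1][violation == "sex"] <- "M"
  old <- s1
  old[s1] <- violation == "age"
  df$dob[old] <- w0 - (2L * sample(10000:12500, sum(old), replace = TRUE) + 1L)
  df
}

#' Analytic expectations under a simulation configuration
#'
#' Closed-form expected sensitivity, specificity and coverage implied by a
#' configuration: sensitivity is the union of the independent evidence
#' channels, `1 - (1 - p1) (1 - p2)`; specificity is one minus the
#' false-recording rate; coverage is
#' `100 (1 - p_undercapture + p_overcapture)` per stratum.
#'
#' @param config a [sim_config()].
#' @return list with `validity` (data frame: criterion, stratum, expected
#'   sens/spec percent) and `coverage` (data frame: stratum, expected
#'   percent).
#' @export
expected_metrics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  types <- c("public", "private")
  rows <- lapply(types, function(s) {
    p1 <- config$record_sens[, s]
    p2 <- config$record_sens2[, s]
    data.frame(
      criterion = CRITERIA, stratum = s,
      sens_pct = 100 * (1 - (1 - p1) * (1 - p2)),
      spec_pct = 100 * (1 - config$record_false_pos[, s]),
      stringsAsFactors = FALSE
    )
  })
  n_h <- c(public = config$n_hospitals_public,
           private = config$n_hospitals_private)
  cov_s <- 100 * (1 - config$p_undercapture + config$p_overcapture)
  cov <- data.frame(
    stratum = c(types, "total"),
    pct = c(cov_s[types], sum(cov_s[types] * n_h) / sum(n_h)),
    stringsAsFactors = FALSE
  )
  list(validity = do.call(rbind, rows), coverage = cov)
}

#' Write simulated tables as delimited files
#'
#' @param sim result of [simulate_claims()].
#' @param dir output directory.
#' @param sep field separator.
#' @return `dir`, invisibly.
#' @export
write_sim_tables <- function(sim, dir, sep = ",") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = sep,
                       row.names = FALSE, quote = FALSE, na = "",
                       fileEncoding = "UTF-8")
  }
  w(sim$reduced, "reduced.csv")
  w(sim$acts, "professional_acts.csv")
  w(sim$reference, "reference.csv")
  invisible(dir)
}
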