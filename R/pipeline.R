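# End-to-end orchestration: ingest -> stage-1 filter -> episode construction
# -> obstetric selection -> professional-acts join -> classification ->
# deterministic linkage of the morbidity subset -> coverage and validity
# reports.

#' Run the full validation pipeline
#'
#' @param reference reference-standard table: one row per hospitalization
#'   with `id`, `cnes`, `hospital_type`, the linkage keys (`dob`,
#'   `admission_date`, `discharge_date`, `race_color`, `postcode`),
#'   `reason`, `discharge_type` and the eleven `flag_*` indicator columns.
#' @param reduced parsed AIH table (the `records` element of
#'   [read_reduced()], or an equivalent data frame).
#' @param acts professional-acts table (`aih_number`, `procedure`).
#' @param rb a `rulebook`.
#' @param passes linkage pass specification.
#' @param thresholds list: `coverage_adequacy` (90), `over_recording` (110),
#'   `reason_missingness` (10), all percentages.
#' @param out_dir if non-`NULL`, report tables are also written there as
#'   tab-separated UTF-8 files.
#' @return list with `flow` (per-stage counts), `stage1`, `episodes`,
#'   `classification`, `link`, `coverage`, `tables` (reason/discharge),
#'   `validity` (per-criterion table) and `linked` (pair-level flags used
#'   for the validity analysis).
#' @export
run_pipeline <- function(reference, reduced, acts, rb = default_rulebook(),
                         passes = default_link_passes(),
                         thresholds = list(coverage_adequacy = 90,
                                           over_recording = 110,
                                           reason_missingness = 10),
                         out_dir = NULL) {
  if (nrow(reference) == 0) stop("linkage stage: empty reference table")
  need <- c("id", "cnes", "hospital_type", "dob", "admission_date",
            "discharge_date", "reason", "discharge_type",
            paste0("flag_", CRITERIA))
  miss <- setdiff(need, names(reference))
  if (length(miss)) stop("reference stage: missing column(s): ",
                         paste(miss, collapse = ", "))

  # stage 1: population filter
  s1 <- stage1_filter(reduced)
  records <- s1$records

  # stage 2: episodes of care
  built <- build_episodes(records)

  # stage 3 + 4: obstetric selection, acts join, classification
  cls <- classify_episodes(records, built, acts = acts, rb = rb)
  obst <- cls$classification$is_obstetric
  episodes <- built$episodes

  # coverage per hospital and stratum (obstetric episodes vs reference)
  type_by_cnes <- tapply(reference$hospital_type, reference$cnes,
                         function(x) x[1])
  index_by_cnes <- table(episodes$cnes[obst])
  ref_by_cnes <- table(reference$cnes)
  cov <- coverage_report(
    stats::setNames(as.integer(index_by_cnes), names(index_by_cnes)),
    stats::setNames(as.integer(ref_by_cnes), names(ref_by_cnes)),
    type_by_cnes,
    adequacy_threshold = thresholds$coverage_adequacy,
    over_threshold = thresholds$over_recording
  )

  # reason / discharge distribution tables
  claims_class <- cbind(episodes[, c("episode_id", "cnes")],
                        cls$classification[, c("reason", "discharge")])
  tables <- reason_discharge_table(
    reference, claims_class[obst, , drop = FALSE],
    missing_threshold = thresholds$reason_missingness
  )

  # linkage: reference morbidity subset vs all obstetric episodes
  ref_flags_all <- as.matrix(reference[, paste0("flag_", CRITERIA)]) > 0
  colnames(ref_flags_all) <- CRITERIA
  morb <- rowSums(ref_flags_all) > 0
  first_rec <- records[match(episodes$first_aih, records$aih_number), ,
                       drop = FALSE]
  ep_keys <- data.frame(
    id = episodes$episode_id,
    cnes = episodes$cnes,
    dob = episodes$dob,
    admission_date = episodes$admission_date,
    discharge_date = episodes$discharge_date,
    race_color = first_rec$race_color,
    postcode = first_rec$postcode,
    stringsAsFactors = FALSE
  )
  ep_keys$race_color[ep_keys$race_color %in% ""] <- NA_character_
  ep_keys$postcode[ep_keys$postcode %in% ""] <- NA_character_
  link <- deterministic_link(ep_keys[obst, , drop = FALSE],
                             reference[morb, , drop = FALSE], passes)

  # validity over linked pairs
  pairs <- link$pairs
  ri <- match(pairs$reference_id, reference$id)
  ei <- match(pairs$episode_id, episodes$episode_id)
  ref_flags <- ref_flags_all[ri, , drop = FALSE]
  claim_flags <- lapply(cls$flags, function(m) m[ei, , drop = FALSE])
  stratum <- reference$hospital_type[ri]
  vt <- validity_table(ref_flags, claim_flags, stratum)

  flow <- list(
    aihs_read = nrow(reduced),
    stage1_kept = nrow(records),
    stage1_exclusions = s1$exclusions,
    episodes = nrow(episodes),
    obstetric_episodes = sum(obst),
    reference_hospitalizations = nrow(reference),
    reference_morbidity = sum(morb),
    linked_morbidity = nrow(pairs)
  )

  out <- list(flow = flow, stage1 = s1, episodes = built,
              classification = cls, link = link, coverage = cov,
              tables = tables, validity = vt,
              linked = list(pairs = pairs, ref_flags = ref_flags,
                            claim_flags = claim_flags, stratum = stratum))
  if (!is.null(out_dir)) write_pipeline_reports(out, out_dir)
  out
}

#' Write pipeline report tables
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_reports <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE, na = "",
                       fileEncoding = "UTF-8")
  }
  w(result$coverage$per_hospital, "coverage_per_hospital.tsv")
  w(result$coverage$per_stratum, "coverage_per_stratum.tsv")
  w(result$tables$reason, "reason_distribution.tsv")
  w(result$tables$discharge, "discharge_distribution.tsv")
  w(result$validity, "validity_by_criterion.tsv")
  w(format_validity_table(result$validity), "validity_by_criterion_print.tsv")
  w(result$link$pairs, "linked_pairs.tsv")
  w(result$episodes$crosswalk, "aih_episode_crosswalk.tsv")
  flow <- result$flow
  flow$stage1_exclusions <- NULL
  w(data.frame(stage = names(flow), count = unlist(flow)), "flow_counts.tsv")
  invisible(out_dir)
}
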