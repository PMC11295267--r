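rb <- default_rulebook()
d <- function(x) as.Date("2021-11-01") + x

classify_one <- function(rec, acts = NULL) {
  built <- build_episodes(rec)
  classify_episodes(rec, built, acts = acts, rb = rb)
}

test_that("obstetric identification accepts any field, any AIH position, or procedure", {
  # chapter-O code on the secondary diagnosis of the *second* AIH
  rec <- rbind(
    aih_rows("A1", admission = d(0), discharge = d(1), billing_reason = "2",
             diag_primary = "B342"),
    aih_rows("A2", admission = d(1), discharge = d(3), diag_primary = "B342")
  )
  rec$diag_secondary3[2] <- "O721"
  res <- classify_one(rec)
  expect_equal(nrow(res$classification), 1L)
  expect_true(res$classification$is_obstetric)

  # no O-code anywhere, non-obstetric procedure: not obstetric
  rec2 <- aih_rows("A1", admission = d(0), discharge = d(1),
                   diag_primary = "J128", primary_procedure = "0303010019")
  expect_false(classify_one(rec2)$classification$is_obstetric)

  # no O-code but an obstetric primary procedure (normal delivery)
  rec3 <- aih_rows("A1", admission = d(0), discharge = d(1),
                   primary_procedure = "0310010012")
  expect_true(classify_one(rec3)$classification$is_obstetric)
  expect_true(is_obstetric_episode(rec3, rb))
})

test_that("reason classification follows the codebook with delivery-procedure override", {
  # vectorized worked examples
  expect_equal(
    classify_reason(
      primary_icd = c("O80", "O141", "O141", "O034", "O860", "J128"),
      procedure = c(NA, "0310010012", "0303100030", "0310010012",
                    NA, "0303100044"),
      has_other_icd = TRUE, rb = rb),
    c("delivery",                 # delivery ICD range O80-O84
      "delivery",                 # delivery procedure overrides complication ICD
      "pregnancy_complication",   # non-delivery procedure, O10-O28 primary
      "abortion",                 # abortive primary beats delivery procedure
      "puerperium_complication",  # O85-O94 primary
      "pregnancy_complication")   # marker procedure for complications
  )
  # residual rule: some other ICD recorded, procedure not a delivery one
  expect_equal(classify_reason("J128", NA, has_other_icd = TRUE, rb = rb),
               "pregnancy_complication")
  expect_equal(classify_reason(NA, NA, has_other_icd = TRUE, rb = rb),
               "pregnancy_complication")
  # nothing recorded at all
  expect_equal(classify_reason(NA, NA, has_other_icd = FALSE, rb = rb),
               "missing")
  # procedure-only episode outside every rule
  expect_equal(classify_reason(NA, "0201010011", has_other_icd = FALSE,
                               rb = rb), "other")
})

test_that("reason uses the first AIH and discharge the last AIH of the episode", {
  rec <- rbind(
    aih_rows("A1", admission = d(0), discharge = d(1), billing_reason = "2",
             diag_primary = "O800", primary_procedure = "0310010012"),
    aih_rows("A2", admission = d(1), discharge = d(4), billing_reason = "6.6",
             diag_primary = "O721")
  )
  res <- classify_one(rec)
  expect_equal(res$classification$reason, "delivery")
  expect_equal(res$classification$discharge, "death")
})

test_that("discharge mapping covers all billing tokens and flags unknown ones", {
  expect_equal(
    classify_discharge(c("6.3", "1", "5", "2", "4", "6.6", "3", ""), rb),
    c("routine", "routine", "administrative", "continuing_stay", "death",
      "death", "transfer", "blank")
  )
  expect_error(classify_discharge("7", rb), "7")
})

test_that("criterion flags count once per episode and record their evidence channel", {
  rec <- rbind(
    aih_rows("A1", admission = d(0), discharge = d(1), billing_reason = "2",
             diag_primary = "O800"),
    aih_rows("A2", admission = d(1), discharge = d(3))
  )
  rec$diag_secondary[1] <- "O141"      # severe pre-eclampsia via ICD
  rec$icu_days[2] <- 3L                # ICU via the stay-days variable
  acts <- data.frame(aih_number = c("A1", "A2"),
                     procedure = c("0306020068", "0306020068"))  # transfusion on both
  res <- classify_one(rec, acts)
  fl <- res$flags
  expect_true(fl$ICD[1, "severe_preeclampsia"])
  expect_false(fl$ICD[1, "hellp"])     # O141 is not the HELLP code
  expect_true(fl$ICU_DAYS[1, "icu"])
  expect_false(fl$PROF_ACT[1, "icu"])
  expect_true(fl$PROF_ACT[1, "transfusion"])
  # transfusion acts on two AIHs of one episode: one episode-level flag
  expect_equal(sum(fl$TOTAL[, "transfusion"]), 1L)
  # channel consistency: TOTAL is the union of the channels
  for (ch in c("ICD", "PROC_REA", "PROF_ACT", "ICU_DAYS")) {
    expect_true(all(fl$TOTAL[fl[[ch]]]))
  }
})

test_that("HELLP and severe pre-eclampsia are distinct criteria", {
  rec <- aih_rows("A1", admission = d(0), discharge = d(1),
                  diag_primary = "O800")
  rec$diag_secondary[1] <- "O142"
  fl <- classify_one(rec)$flags
  expect_true(fl$TOTAL[1, "hellp"])
  expect_false(fl$TOTAL[1, "severe_preeclampsia"])
})

test_that("adding an AIH to an episode never clears a flag", {
  rec1 <- aih_rows("A1", admission = d(0), discharge = d(1),
                   billing_reason = "2", diag_primary = "O800")
  rec1$diag_secondary[1] <- "O450"
  fl1 <- classify_one(rec1)$flags
  rec2 <- rbind(rec1, aih_rows("A2", admission = d(1), discharge = d(3)))
  fl2 <- classify_one(rec2)$flags
  expect_true(all(fl2$TOTAL[1, ][fl1$TOTAL[1, ]]))
  expect_true(fl2$TOTAL[1, "abruptio_placentae"])
})
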