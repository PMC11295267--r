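test_that("rounding is half-away-from-zero at the printed precision", {
  expect_equal(round_half_away(0.25, 1), 0.3)
  expect_equal(round_half_away(0.15, 1), 0.2)
  expect_equal(round_half_away(-0.25, 1), -0.3)
  expect_equal(round_half_away(95.05, 1), 95.1)
  expect_equal(round_half_away(c(0.105, 0.115), 2), c(0.11, 0.12))
})

test_that("coverage reproduces the published study arithmetic", {
  total <- coverage(32212, 33867)
  expect_equal(total$pct, 95.1)
  expect_true(total$adequate)
  public <- coverage(22176, 22125)
  expect_equal(public$pct, 100.2)
  expect_true(public$adequate)
  expect_false(public$over_recording)
  private <- coverage(10036, 11742)
  expect_equal(private$pct, 85.5)
  expect_false(private$adequate)
  expect_true(coverage(120, 100)$over_recording)
  expect_true(coverage(90, 100)$adequate)            # threshold inclusive
  expect_false(coverage(110, 100)$over_recording)    # >110 is over-recording
  expect_error(coverage(10, 0), "positive")
})

test_that("confusion counts come straight from paired flags", {
  ref <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  idx <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)
  ct <- confusion(ref, idx)
  expect_equal(ct$tp, 2L)
  expect_equal(ct$fn, 1L)
  expect_equal(ct$fp, 1L)
  expect_equal(ct$tn, 3L)
  v <- validity(ct)
  expect_equal(v$sens, 2 / 3)
  expect_equal(v$spec, 3 / 4)
  expect_error(confusion(ref, idx[-1]), "length")
})

test_that("likelihood ratios reproduce the published worked examples", {
  # computed from the printed sensitivity/specificity percentages
  ex <- list(
    list(sens = 38.0, spec = 97.4, lr_neg = 0.64),  # severe pre-eclampsia, total
    list(sens = 33.7, spec = 96.4, lr_pos = 9.4),   # severe pre-eclampsia, private
    list(sens = 50.4, spec = 97.5, lr_neg = 0.51),  # transfusion, total
    list(sens = 20.2, spec = 98.5, lr_neg = 0.81)   # eclampsia, public
  )
  for (e in ex) {
    v <- validity(sens = e$sens / 100, spec = e$spec / 100)
    if (!is.null(e$lr_neg)) {
      expect_equal(round_half_away(v$lr_neg, 2), e$lr_neg)
    }
    if (!is.null(e$lr_pos)) {
      expect_equal(round_half_away(v$lr_pos, 1), e$lr_pos)
    }
  }
})

test_that("degenerate cells map to the documented sentinels", {
  perfect <- validity(confusion(c(TRUE, FALSE), c(TRUE, FALSE)))
  expect_identical(perfect$lr_pos, Inf)          # no false positives
  expect_equal(sihvalid:::format_lr_pos(perfect$lr_pos), "–")
  expect_equal(perfect$lr_neg, 0)
  inverse <- validity(confusion(c(TRUE, FALSE), c(FALSE, TRUE)))
  expect_true(is.na(inverse$lr_neg))             # specificity zero
  expect_equal(sihvalid:::format_lr_neg(inverse$lr_neg), "–")
  expect_error(validity(confusion(logical(2), c(TRUE, FALSE))), "positives")
  expect_error(validity(confusion(c(TRUE, TRUE), c(TRUE, FALSE))), "negatives")
})

test_that("interpretation bands follow the printed cutoffs at print precision", {
  # positive-LR bands
  expect_equal(interpret(lr_pos = 12.3)$band_pos, "strong")
  expect_equal(interpret(lr_pos = 9.95)$band_pos, "strong")   # prints as 10.0
  expect_equal(interpret(lr_pos = 9.94)$band_pos, "moderate") # prints as 9.9
  expect_equal(interpret(lr_pos = 5.0)$band_pos, "moderate")
  expect_equal(interpret(lr_pos = 4.94)$band_pos, "weak")
  expect_equal(interpret(lr_pos = 2.0)$band_pos, "weak")
  expect_equal(interpret(lr_pos = 1.9)$band_pos, "very weak")
  expect_equal(interpret(lr_pos = 1.0)$band_pos, "very weak")
  expect_equal(interpret(lr_pos = Inf)$band_pos, "strong")
  # negative-LR bands; 0.10 sits in the strong band
  expect_equal(interpret(lr_neg = 0.08)$band_neg, "strong")
  expect_equal(interpret(lr_neg = 0.10)$band_neg, "strong")
  expect_equal(interpret(lr_neg = 0.104)$band_neg, "strong")  # prints as 0.10
  expect_equal(interpret(lr_neg = 0.11)$band_neg, "moderate")
  expect_equal(interpret(lr_neg = 0.20)$band_neg, "moderate")
  expect_equal(interpret(lr_neg = 0.21)$band_neg, "weak")
  expect_equal(interpret(lr_neg = 0.50)$band_neg, "weak")
  expect_equal(interpret(lr_neg = 0.51)$band_neg, "very weak")
  expect_equal(interpret(lr_neg = 1.0)$band_neg, "very weak")
  expect_true(is.na(interpret(lr_neg = NA_real_)$band_neg))
})

test_that("likelihood ratios are monotone in sensitivity and specificity", {
  set.seed(5)
  for (i in 1:50) {
    sens <- runif(1, 0.05, 0.95)
    spec <- runif(1, 0.55, 0.99)
    base <- validity(sens = sens, spec = spec)
    up_sens <- validity(sens = min(sens + 0.02, 1), spec = spec)
    up_spec <- validity(sens = sens, spec = min(spec + 0.005, 1))
    expect_gte(up_sens$lr_pos, base$lr_pos)
    expect_lte(up_sens$lr_neg, base$lr_neg)
    expect_gte(up_spec$lr_pos, base$lr_pos)
    expect_lte(up_spec$lr_neg, base$lr_neg)
  }
})

test_that("hospitals above the missing-reason threshold are excluded", {
  ref <- data.frame(
    cnes = rep(c("H1", "H2", "H3"), times = c(10, 100, 100)),
    reason = c(rep("delivery", 9), NA,                # 10.0% missing: kept
               rep("delivery", 89), rep(NA, 11),      # 11% missing: excluded
               rep("delivery", 100)),                 # complete: kept
    stringsAsFactors = FALSE
  )
  kept <- missingness_exclusion(ref)
  expect_setequal(kept, c("H1", "H3"))
  # empty-string reasons count as missing too
  ref$reason[ref$cnes == "H3"][1:12] <- ""
  expect_setequal(missingness_exclusion(ref), "H1")
})
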