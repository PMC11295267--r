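---
title: "Validating obstetric hospitalization claims against a reference census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating obstetric hospitalization claims against a reference census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(sihvalid)
```

## The problem

Brazil's public hospital system bills every admission through a Hospital
Admission Authorization (AIH). The national hospital information system
(SIH/SUS) built from these billing records is a tempting surveillance source
for severe maternal morbidity: it is universal, cheap and timely. But it is
a billing system, not a clinical registry, so two questions must be
answered before using it for surveillance:

1. **Coverage** — what share of real obstetric hospitalizations leave any
   trace in the claims at all?
2. **Validity** — when a life-threatening complication actually happened,
   how often do the claims record it (sensitivity), and when it did not,
   how often do they stay silent (specificity)?

`sihvalid` implements the full validation pipeline: it reconstructs
hospital stays from AIH billing rows, classifies them with a declarative
rulebook of ICD-10 and SIGTAP code sets, links them deterministically to a
reference-standard census of obstetric hospitalizations, and computes
stratified coverage and diagnostic-validity tables. A configurable
synthetic-data generator with known ground truth closes the loop: every
stage can be checked against what the generator actually did.

## From billing rows to episodes of care

One hospital stay may be billed as several chained AIHs: an AIH closed with
the "continuing inpatient stay" billing reason is followed by a fresh AIH
at the same facility. The pipeline therefore works on *episodes of care*,
not raw AIHs.

The population filter (`stage1_filter()`) first keeps type-1 AIHs of women
aged 10–49 at admission. Age is computed from date of birth when available
and falls back to the recorded age otherwise; date of birth doubles as a
linkage key, so it is the more trustworthy field.

`build_episodes()` then partitions the remaining rows within a person key
(facility code + date of birth). Two consecutive AIHs belong to the same
episode when the earlier one carries the continuing-stay token and the next
admission follows the earlier discharge by at most one day
(`chain_predicate()`). Chaining is greedy-chronological: the earliest
unassigned AIH opens an episode and is extended maximally, each step taking
the earliest eligible unassigned AIH (ties broken by smallest AIH number).
A continuing-stay token with no eligible successor is flagged
`unresolved_continuation` rather than guessed at.

Two properties are worth stating precisely, because the tests rely on them:

* The result is a valid partition: every consecutive pair inside an episode
  satisfies the chaining predicate, and the partition does not depend on
  input row order.
* Chains are *maximal*, not *minimum in number*. In real data chained AIHs
  are sequential and the two notions coincide; in adversarial synthetic
  configurations with several overlapping same-day AIHs under one person
  key, greedy maximal chaining can produce more episodes than the smallest
  possible partition. The test suite checks the builder against a plain
  reference restatement of the greedy rule plus brute-force enumeration of
  all valid partitions, not against minimality.

## The rulebook

All clinical code sets live in one declarative YAML document (the
*rulebook*), shipped as `inst/extdata/box1_default.yaml` and loaded with
`default_rulebook()`. It defines:

* **Obstetric identification** — an episode is obstetric when any of its
  AIHs carries a chapter-O ICD-10 code in any of the fourteen diagnosis
  fields, or an obstetric SIGTAP procedure (30 codes) as primary procedure.
* **Reason for hospitalization** — classified from the *first* AIH of the
  episode: abortion-related codes first, then delivery (by ICD or by one of
  seven delivery procedures), then specific pregnancy-complication and
  puerperium-complication codes, and finally a residual rule that assigns
  any other recorded diagnosis to pregnancy complication unless a delivery
  procedure is present. Specific rules run before the residual catch-all so
  that every category is reachable.
* **Discharge type** — mapped from the billing-reason token of the *last*
  AIH (routine, administrative, continuing stay, death, transfer, blank).
* **Eleven morbidity criteria** — seven diagnoses (severe pre-eclampsia,
  eclampsia, HELLP syndrome, abruptio placentae, hemorrhage, uterine
  rupture, ectopic pregnancy) with pairwise-disjoint ICD sets, and four
  procedures (hysterectomy, laparotomy, blood-product transfusion, ICU
  admission) identified by SIGTAP code sets, with ICU additionally
  identified by the ICU stay-days variable of the reduced database.

`classify_episodes()` evaluates the criteria once per episode and records
*where* each flag came from: any diagnosis field of any AIH (`ICD`), the
primary procedure (`PROC_REA`), the professional-services acts joined by
AIH number (`PROF_ACT`), or the ICU stay-days variable (`ICU_DAYS`). The
`TOTAL` channel is their union. Because the stay-days variable lives in the
reduced database, the report table folds it into the reduced-database
column.

## Linkage and metrics

`deterministic_link()` matches obstetric episodes to reference stays in
four passes over six keys (facility code, date of birth, admission date,
discharge date, race/colour, postcode). Later passes drop postcode, then
race/colour, then allow the discharge date to differ by one day (split
billing shifts it). Missing key values never satisfy equality, and any key
block with several candidates on either side is left unmatched and counted
as an ambiguity — a deliberate precision-over-recall choice, since a wrong
link poisons both a sensitivity and a specificity cell.

Coverage is the claims-side count as a percentage of the reference count
(at least 90% adequate, above 110% flags over-recording). Validity is
computed over linked reference stays with at least one morbidity criterion.
Likelihood ratios follow the standard definitions,
LR+ = sens/(1−spec) and LR− = (1−sens)/spec, with two conventions chosen to
reproduce the published report format exactly:

* All percentages and ratios round half *away from zero*
  (`round_half_away()`), not banker's rounding; LR+ prints with one
  decimal, LR− with two.
* Interpretation bands are assigned on the value rounded to its printing
  precision: LR+ ≥ 10 strong, 5–9.9 moderate, 2–4.9 weak, 1–1.9 very weak;
  LR− ≤ 0.10 strong, 0.11–0.20 moderate, 0.21–0.50 weak, 0.51–1 very weak.
  The strong LR− band deliberately includes 0.10 itself, matching how
  published values at that boundary are described. With no false positives
  LR+ is infinite and prints as a dash; with no true negatives LR− is
  undefined.

## The synthetic generator

`simulate_claims()` draws a hospital census with known ground truth and
then corrupts the claims side with configurable error processes. The
default `sim_config()` mirrors the validated study setting: 50 public and
28 private hospitals, 430 obstetric stays each over a 30-day window,
per-criterion prevalence, recording sensitivity and false-positive rates
per stratum, under-capture concentrated in private hospitals (14.5%),
slight over-capture in public ones (0.2%), 3% split billing, and 5%
missingness in the postcode and race/colour keys.

Every error process is explicit and independently switchable:

* `record_sens` / `record_false_pos` — probability a true condition is
  recorded / a false code appears, per criterion and stratum. Each
  criterion is written through one realistic evidence channel (diagnosis
  fields for the seven diagnoses, professional acts for the surgical
  procedures and transfusion, stay-days for ICU); an optional second
  channel (`record_sens2`) combines by the union rule
  `1 − (1 − p1)(1 − p2)`, and `expected_metrics()` returns the closed-form
  expectations for any configuration.
* `p_undercapture` / `p_overcapture` — stays producing no AIH / spurious
  claims-only stays, which drive coverage below or above 100%.
* `p_split` — stays billed as two chained AIHs, exercising the episode
  builder.
* `p_key_missing` / `p_key_corrupt` — linkage-key degradation, exercising
  the relaxation passes.
* Decoy rows that the stage-1 filter and the obstetric selection must
  reject.

Realism has limits, by design. Dates of birth are drawn *without
replacement* within a hospital (even day-offsets for stays, odd for
decoys), so person keys never collide; real data has twins, namesakes and
shared birthdays, which the conservative ambiguity handling addresses but
the generator does not produce. Prevalences are independent across
criteria, whereas real severe-morbidity conditions co-occur. Evidence
channels are assigned per criterion instead of mixed. These choices make
parameter recovery exactly interpretable — estimated sensitivity converges
on `record_sens` — at the cost of understating real-world linkage
difficulty.

With every error process switched off, the pipeline must reproduce the
reference exactly — 100.0% coverage, perfect sensitivity and specificity,
exact recovery of the ground-truth pairing — and the acceptance suite
checks precisely that, alongside recovery of non-trivial error rates to
within three binomial standard errors.

## A minimal run

```{r pipeline}
cfg <- sim_config(seed = 1L, n_hospitals_public = 4L,
                  n_hospitals_private = 3L, episodes_per_hospital = 60L)
sim <- simulate_claims(cfg)
res <- run_pipeline(sim$reference, sim$reduced, sim$acts)
res$coverage$per_stratum[, c("stratum", "n_index", "n_ref", "pct")]
head(format_validity_table(res$validity)[, c("criterion", "stratum",
                                             "sens", "spec",
                                             "lr_neg", "lr_pos")])
```

The numbered scripts under `analysis/` run the same flow at the full
default scale and write all report tables under `results/`.
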