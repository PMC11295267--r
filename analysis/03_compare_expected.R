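#!/usr/bin/env Rscript
# Compare the estimated validity metrics from 02_run_pipeline.R with the
# closed-form expectations implied by the generator configuration from
# 01_simulate.R, and summarize the agreement.

suppressMessages(library(sihvalid))

est <- read.delim(file.path("results", "reports",
                            "validity_by_criterion.tsv"))
exp_v <- read.delim(file.path("results", "data", "expected_validity.tsv"))
exp_c <- read.delim(file.path("results", "data", "expected_coverage.tsv"))
cov <- read.delim(file.path("results", "reports",
                            "coverage_per_stratum.tsv"))

cmp <- merge(est[, c("criterion", "stratum", "n_linked", "n_ref_pos",
                     "sens_pct", "spec_pct")],
             exp_v, by = c("criterion", "stratum"),
             suffixes = c("_est", "_exp"))
cmp$sens_diff <- cmp$sens_pct_est - cmp$sens_pct_exp
cmp$spec_diff <- cmp$spec_pct_est - cmp$spec_pct_exp
# binomial standard errors at the expected rates
cmp$sens_se <- 100 * sqrt(cmp$sens_pct_exp / 100 *
                            (1 - cmp$sens_pct_exp / 100) / cmp$n_ref_pos)
cmp$spec_se <- 100 * sqrt(cmp$spec_pct_exp / 100 *
                            (1 - cmp$spec_pct_exp / 100) /
                            (cmp$n_linked - cmp$n_ref_pos))
cmp <- cmp[order(cmp$criterion, cmp$stratum), ]

cov_cmp <- merge(cov[, c("stratum", "pct")], exp_c, by = "stratum",
                 suffixes = c("_est", "_exp"))
cov_cmp$diff <- cov_cmp$pct_est - round_half_away(cov_cmp$pct_exp, 1)

out <- file.path("results", "expected_vs_estimated_validity.tsv")
write.table(cmp, out, sep = "\t", row.names = FALSE, quote = FALSE)
write.table(cov_cmp,
            file.path("results", "expected_vs_estimated_coverage.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

cat("validity: largest |sens diff| =",
    round(max(abs(cmp$sens_diff), na.rm = TRUE), 1), "pp;",
    "largest |sens diff| / SE =",
    round(max(abs(cmp$sens_diff / cmp$sens_se), na.rm = TRUE), 2), "\n")
cat("coverage differences (estimated - expected, pp):\n")
print(cov_cmp, row.names = FALSE)
cat("written to", out, "\n")
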