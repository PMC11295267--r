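#!/usr/bin/env Rscript
# Generate the synthetic study dataset under the default configuration:
# 50 public + 28 private hospitals, 430 obstetric stays each over a 30-day
# window, with recording error rates per criterion and stratum. Writes the
# three claims/reference tables and the analytic expectations.

suppressMessages(library(sihvalid))

out_dir <- file.path("results", "data")
cfg <- sim_config(seed = 20212022L)
sim <- simulate_claims(cfg)
write_sim_tables(sim, out_dir)

ex <- sim$truth$expected
write.table(ex$validity, file.path(out_dir, "expected_validity.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(ex$coverage, file.path(out_dir, "expected_coverage.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

cat("stays:", nrow(sim$reference),
    "| AIH rows:", nrow(sim$reduced),
    "| act rows:", nrow(sim$acts), "\n")
cat("written to", out_dir, "\n")
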