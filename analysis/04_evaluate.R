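#!/usr/bin/env Rscript
# Step 4 -- the validation analysis.
#
# Agreement of combined-database scores with each population database and
# with visual scores; Kruskal-Wallis contrasts of HMR and automated score
# across CAD / DCM / no-disease; ROC for each marker and for the logistic
# combination of HMR with the automated score. Writes the full report
# as JSON and prints the headline numbers.

suppressPackageStartupMessages(library(mibgndb))

jp <- read_profiles("results/cohort_jp_normals.csv")
it <- read_profiles("results/cohort_it_normals.csv")
val <- read_profiles("results/cohort_validation.csv")

report <- suppressMessages(run_validation_pipeline(jp, it, val))
write_report(report, "results/evaluation_report.json")

print(report)
for (ph in c("early", "late")) {
  r <- report[[ph]]
  message(sprintf(
    "%s: combined model coefficients (intercept %.2f, HMR %.2f, score %.2f)",
    ph, r$combined$coefficients[1], r$combined$coefficients[2],
    r$combined$coefficients[3]))
}
message("report written to results/evaluation_report.json")
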