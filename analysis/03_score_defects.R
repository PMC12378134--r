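#!/usr/bin/env Rscript
# Step 3 -- score the validation cohort.
#
# Automated database-relative scores against the Jp, It and combined
# databases, plus the visual percent-count banding rule, per phase.
# Writes one long score table with the summed score per subject.

suppressPackageStartupMessages(library(mibgndb))

val <- read_profiles("results/cohort_validation.csv")

tabs <- list()
for (ph in c("early", "late")) {
  v <- val[val$phase == ph, ]
  for (pop in c("Jp", "It", "JpIt")) {
    ndb <- read_ndb(sprintf("results/ndb_%s_%s.csv", pop, ph))
    tabs[[paste(pop, ph)]] <- score_cohort(v, "ndb_auto", ndb)
  }
  tabs[[paste("visual", ph)]] <- score_cohort(v, "visual_rule")
}
scores <- do.call(rbind, tabs)
rownames(scores) <- NULL
write.csv(scores, "results/defect_scores.csv", row.names = FALSE)

late <- scores[scores$phase == "late" & scores$method == "ndb_auto" &
                 scores$ndb_id == "JpIt", ]
message("late-phase mean summed score (JpIt automated) by group:")
for (g in c("none", "CAD", "DCM"))
  message(sprintf("  %-5s %.1f", g, mean(late$summed[late$label == g])))
message("score table written to results/defect_scores.csv")
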