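#!/usr/bin/env Rscript
# Reliability study: two simulated raters segment every patient twice (a
# week apart) by warping the true labeled volume with a smooth 0.2 mm
# displacement field; the deltoid internal surface is re-extracted and the
# ILSS refitted each time. Intra- and inter-rater agreement is summarised
# with two-way absolute-agreement ICCs over patients.

suppressPackageStartupMessages(library(coaptR))
dir.create("results", showWarnings = FALSE)
seed <- 1L

cohort <- synthetic_cohort(radii = reference_ilss_radii(), seed = seed)
study <- simulate_rater_study(cohort, noise_sd = 0.2, seed = seed)
write.csv(study, "results/rater_study.csv", row.names = FALSE)

agr <- rbind(agreement_table(study, model = "ICC2"),
             agreement_table(study, model = "ICC3"))
write.csv(agr, "results/agreement_table.csv", row.names = FALSE)

cat("Repeat-segmentation agreement (ICC over patients):\n")
print(as.data.frame(agr), row.names = FALSE, digits = 4)
cat(sprintf("\nAll ICC(2,1) >= %.3f; the published reliability study reports\n",
            min(agr$icc[agr$model == "ICC2"])))
cat("values of the same order (0.93-0.999) on real repeat segmentations.\n")
cat("Wrote results/rater_study.csv and results/agreement_table.csv\n")
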