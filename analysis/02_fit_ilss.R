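#!/usr/bin/env Rscript
# Fit the implant least-squares sphere (ILSS) to each patient's deltoid
# internal-aspect cloud with the iterative normal-filter / prune / refit
# loop, and compare fitted radii with the generating (published) radii.

suppressPackageStartupMessages(library(coaptR))
dir.create("results", showWarnings = FALSE)
seed <- 1L

radii <- reference_ilss_radii()
cohort <- synthetic_cohort(radii = radii, seed = seed)
rows <- lapply(seq_along(cohort), function(i) {
  gen <- generate_shoulder(cohort[[i]], seed = seed + i, with_volume = FALSE)
  fit <- iterate_fit(gen$clouds$deltoid)
  data.frame(patient = names(radii)[i], true_radius = radii[[i]],
             fitted_radius = fit$sphere$radius,
             iterations = nrow(fit$diagnostics),
             points_used = nrow(fit$cloud$points))
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/ilss_radii.csv", row.names = FALSE)

d <- descriptives(tab$fitted_radius)
cat("Per-patient ILSS fits (noiseless clouds):\n")
print(tab, row.names = FALSE, digits = 6)
cat(sprintf("Mean fitted radius: %s mm (published summary: 32.89±4.29 mm)\n",
            format_descriptives(d)))
cat(sprintf("Max |fitted - true| radius error: %.2e mm\n",
            max(abs(tab$fitted_radius - tab$true_radius))))
cat("Wrote results/ilss_radii.csv\n")
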