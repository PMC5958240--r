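#!/usr/bin/env Rscript
# Sarcomeric incorporation from fluorescence line scans: segmentation on
# the boundary minima, alignment on the central (M-line) minimum,
# two-level averaging (sarcomeres within myofibril, then across
# myofibrils), peak metrics, and Welch comparisons vs WT.

suppressPackageStartupMessages(library(ccrod))
out <- "results/sarcomere"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 606L

presets <- scenario_presets()
mets <- list()
for (sc in c("WT", "A1603P", "K1617del")) {
  p <- presets[[sc]]$sarcomere
  scans <- gen_linescans(n_myofibrils = 12,
                         peak_amplitude = p[["peak_amplitude"]],
                         m_line_amplitude = p[["m_line_amplitude"]],
                         seed = seed + match(sc, names(presets)))
  mets[[sc]] <- sarcomere_metrics_by_myofibril(scans, sc)
  # averaged profile of the first myofibril for the record
  wins <- segment_sarcomeres(scans[[1]]$position, scans[[1]]$intensity)
  prof <- align_average(wins, myofibril = rep(1, length(wins)))
  write.csv(prof, file.path(out, paste0("profile_", sc, ".csv")),
            row.names = FALSE)
}
met <- do.call(rbind, c(mets, make.row.names = FALSE))
cmp <- compare_profile_groups(met)
write.csv(met, file.path(out, "myofibril_metrics.csv"), row.names = FALSE)
write.csv(cmp, file.path(out, "group_comparison.csv"), row.names = FALSE)
print(cmp, row.names = FALSE, digits = 4)
cat("\nBoth mutants accumulate signal at the M-line (lower peak/min",
    "ratio than WT); K1617del also shows lower peak values,",
    "mirroring its weaker sarcomeric incorporation.\n")
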