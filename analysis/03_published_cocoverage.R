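#!/usr/bin/env Rscript
# Recompute co-coverage summary statistics from the published percentage
# distributions shipped with the package (15 DHS surveys, 2015-2018):
# for each country, the mean and population SD of the co-coverage index
# implied by its printed 0-5 distribution, and the combined coverage +
# quality-coverage gap (the percentage of newborns without all five
# interventions). Writes results/published_cocoverage_summary.csv.
#
# Note: the printed cells carry 1-decimal rounding, so a recomputed SD can
# differ from a reported SD by about 0.01 where the rounding error
# propagates (Burundi, Ethiopia); the means all agree at printed precision.

library(pnccoverage)

tab <- read.csv(system.file("extdata", "reported_cocoverage_15countries.csv",
                            package = "pnccoverage"))

summary <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
  cc <- cocoverage_from_shares(as.numeric(tab[i, paste0("p", 0:5)]))
  data.frame(
    country = tab$country[i],
    mean_recomputed = cc$mean,
    sd_recomputed = cc$sd,
    mean_reported = tab$mean_reported[i],
    sd_reported = tab$sd_reported[i],
    combined_gap_pct = 100 * (1 - cc$shares[["p5"]]),
    mean_matches = round(cc$mean, 1) == tab$mean_reported[i],
    sd_matches = round(cc$sd, 2) == tab$sd_reported[i]
  )
}))

dir.create("results", showWarnings = FALSE)
write.csv(summary, file.path("results", "published_cocoverage_summary.csv"),
          row.names = FALSE)

cat("Recomputed co-coverage mean (SD) vs reported, and combined gap:\n")
for (i in seq_len(nrow(summary))) {
  cat(sprintf("  %-9s %4.1f (%.2f)  reported %4.1f (%.2f)  combined gap %5.1f%%%s\n",
              summary$country[i], summary$mean_recomputed[i],
              summary$sd_recomputed[i], summary$mean_reported[i],
              summary$sd_reported[i], summary$combined_gap_pct[i],
              if (summary$sd_matches[i]) "" else "   [SD differs: cell rounding]"))
}
cat(sprintf("\n%d/15 means and %d/15 SDs reproduce at printed precision.\n",
            sum(summary$mean_matches), sum(summary$sd_matches)))
cat(sprintf("Combined gap ranges from %.1f%% (%s) to %.1f%% (%s).\n",
            min(summary$combined_gap_pct),
            summary$country[which.min(summary$combined_gap_pct)],
            max(summary$combined_gap_pct),
            summary$country[which.max(summary$combined_gap_pct)]))
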