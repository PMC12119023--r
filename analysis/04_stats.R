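#!/usr/bin/env Rscript
# Inference battery over the simulated study design: baseline stability
# (Friedman per group), WT vs APP baseline comparisons (Mann-Whitney U with
# mean ranks and eta-squared), pre-stimulation density (mixed ANOVA with
# Greenhouse-Geisser correction), and post- vs pre-stimulation turnover
# (Wilcoxon signed-rank, Bonferroni-adjusted alpha over the four post days).

suppressPackageStartupMessages(library(boutondyn))
dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)

density <- read_table("results/dynamics/density.csv", "density")
intervals <- read_table("results/dynamics/intervals.csv", "intervals")

results <- stats_battery(density, intervals, stim_session = 5,
                         alpha = 0.05, m = 4)
write_table(results, "results/stats/results.csv", "results")

# headline comparisons, reported in the conventional style
for (type in c("TB", "EPB")) {
  iv <- intervals[intervals$type == type, ]
  sp <- baseline_post_split(iv, "turnover", stim_session = 5)
  b <- sp$baseline
  groups <- sort(unique(b$group))
  mw <- mann_whitney_u(b$value[b$group == groups[1]],
                       b$value[b$group == groups[2]])
  message(sprintf("%s baseline turnover, %s vs %s: %s",
                  type, groups[1], groups[2], format_rank_test(mw)))
}

post <- results[results$family == "post_vs_baseline" &
                  results$measure == "turnover", ]
for (i in seq_len(nrow(post))) {
  message(sprintf("turnover %-18s Z=%.2f p=%.3f %s",
                  post$comparison[i], post$value[i], post$p[i],
                  ifelse(post$significant[i], "*", "ns")))
}
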