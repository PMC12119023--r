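#!/usr/bin/env Rscript
# Dynamics stage over the simulated study design: per-session bouton
# densities and per-interval turnover / gain / loss fractions for every
# axon, labelled by imaging day (-8 .. +8, stimulation after day 0).

suppressPackageStartupMessages(library(boutondyn))
dir.create("results/dynamics", recursive = TRUE, showWarnings = FALSE)

tracks <- read_table("results/sim/truth_tracks.csv", "tracks")
axons <- read_table("results/sim/axons.csv", "axons")
days <- session_days(world_preset("wt_tb"))
lens <- setNames(axons$length_um, axons$axon_id)

dyn <- axon_dynamics(tracks, lens, n_sessions = 9, days = days)
density <- cbind(dyn$density,
                 axons[match(dyn$density$axon_id, axons$axon_id),
                       c("group", "type")])
intervals <- cbind(dyn$intervals,
                   axons[match(dyn$intervals$axon_id, axons$axon_id),
                         c("group", "type")])
write_table(density, "results/dynamics/density.csv", "density")
write_table(intervals, "results/dynamics/intervals.csv", "intervals")

for (type in c("TB", "EPB")) {
  for (g in unique(density$group)) {
    sel <- density$type == type & density$group == g
    pre <- intervals$type == type & intervals$group == g &
      intervals$session_b <= 5
    message(sprintf(
      "%-3s %-8s mean density %.3f per um, baseline turnover %.3f",
      type, g, mean(density$density_per_um[sel]),
      mean(intervals$turnover[pre], na.rm = TRUE)))
  }
}
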