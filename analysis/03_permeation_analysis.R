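#!/usr/bin/env Rscript
# Stage 3: permeation statistics of the stage-2 trajectory: events,
# cumulative fluxes, rates, K+/Na+ selectivity, conduction-mode mixture
# and knock-on annotations.  The trajectory is re-read from disk to
# exercise the same path an external (MD-derived) trajectory would take.

library(cntkchan)

inp <- "results/simulate"
out <- "results/permeation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
stopifnot(file.exists(file.path(inp, "trajectory.xyz")))

traj <- read_trajectory(file.path(inp, "trajectory.xyz"))
geom <- channel_geometry()

events <- detect_events(traj, geom)
truth <- read.delim(file.path(inp, "events_truth.tsv"))
cat(sprintf("detected %d events (ground truth %d): %d K+, %d Na+\n",
            nrow(events), nrow(truth), sum(events$species == "K"),
            sum(events$species == "Na")))

total_time <- traj$n_frames * traj$dt
flux <- cumulative_flux(events, total_time, field_strength = 0.2)
rate_k <- permeation_rate(flux, "K")
rate_na <- permeation_rate(flux, "Na")
sr <- selectivity_ratio(rate_k$rate_per_s, rate_na$rate_per_s,
                        rate_na$n, total_time)
cat(sprintf("rates over %.0f ns: K+ %.3g /s, Na+ %.3g /s, SR %.1f (%s)\n",
            total_time, rate_k$rate_per_s, rate_na$rate_per_s,
            sr$sr, sr$qualifier))

cm <- classify_modes(events, traj, geom)
cat(sprintf("modes over %d classified K+ events: mode 1 %.1f%%, mode 2 %.1f%%\n",
            cm$n_classified, 100 * cm$fractions[["mode1"]],
            100 * cm$fractions[["mode2"]]))

ko <- detect_knock_on(events, traj, geom)
cat(sprintf("%d knock-on transitions annotated (%d on Na+)\n",
            nrow(ko), sum(ko$ion_id == "Na1")))

write.table(cm$events, file.path(out, "events.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(flux, file.path(out, "flux.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(ko, file.path(out, "knock_on.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("wrote", out, "\n")
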