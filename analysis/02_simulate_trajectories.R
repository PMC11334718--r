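#!/usr/bin/env Rscript
# Stage 2: synthetic data with known ground truth.
#
# (a) A stochastic knock-on permeation trajectory under the packaged
#     low-field KCl/NaCl mixture (76% mode-1 entries, rare off-axis Na+).
# (b) Umbrella-window samples over both packaged two-binding-site
#     reference landscapes, with the standard protocol (-10..10 A every
#     0.5 A, 20 kcal/mol/A^2, 300 K, half the chain as equilibration).

library(cntkchan)

out <- "results/simulate"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- generate_permeation_trajectory(kcl_mix_0p2V(n_events = 500,
                                                     seed = 1))
cat(sprintf("trajectory: %d frames x %d particles, %d ground-truth events (%d Na+)\n",
            sim$trajectory$n_frames,
            round(nrow(sim$trajectory$atoms) / sim$trajectory$n_frames),
            nrow(sim$events), sum(sim$events$species == "Na")))
write_xyz(sim$trajectory, file.path(out, "trajectory.xyz"))
write.table(sim$events, file.path(out, "events_truth.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

for (profile in c("na_two_site", "k_two_site")) {
  ref <- reference_pmf_profile(profile)
  windows <- generate_umbrella_samples(ref, umbrella_protocol(seed = 1))
  meta <- write_umbrella_windows(windows,
                                 file.path(out, "umbrella", profile))
  cat(sprintf("%s: %d windows x %d samples -> %s\n", profile,
              length(windows), windows[[1]]$n_effective, meta))
  write.table(data.frame(z = seq(-12, 12, 0.1),
                         energy = eval_pmf(ref, seq(-12, 12, 0.1))),
              file.path(out, paste0("reference_", profile, ".tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
}

cat("wrote", out, "\n")
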