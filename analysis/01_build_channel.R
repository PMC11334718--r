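#!/usr/bin/env Rscript
# Stage 1: construct the biomimetic channel and the solvated membrane
# system.
#
# Recipe: armchair (7,7) tube (0.95 nm diameter), 10% axial strain
# (ring spacing 2.45 -> ~2.7 A), 13.34 A mid-section, 20 inward carbonyl
# oxygens in four rings (+-0.51 e pairs), embedded between two pored
# graphene sheets in a 5.1 nm box of 0.5 M KCl + 0.5 M NaCl.

library(cntkchan)

out <- "results/build"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- cnt_spec()
tube <- build_cnt(spec)
cat(sprintf("pristine (7,7) tube: %d atoms, diameter %.2f nm, ring spacing %.2f A\n",
            nrow(tube), attr(tube, "diameter") / 10, ring_spacing(tube)))

channel <- build_channel(spec)
cat(sprintf("decorated channel: %d atoms, %d carbonyl O, ring spacing %.2f A, net charge %+.2f e\n",
            nrow(channel), sum(channel$tag == "carbonyl_O"),
            ring_spacing(channel), net_charge(channel)))

write_pdb(channel, file.path(out, "channel.pdb"))
write_xyz(channel, file.path(out, "channel.xyz"))
write_charge_table(channel, file.path(out, "channel_charges.tsv"))

sys <- assemble_membrane_system(channel, seed = 1)
print(sys)
allat <- system_to_atomset(sys)
cat(sprintf("full system: %d atoms, net charge %+.3f e\n",
            nrow(allat), net_charge(allat)))
write_pdb(allat, file.path(out, "system.pdb"))

cat("wrote", out, "\n")
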