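#!/usr/bin/env Rscript
# Stage 5: DNA-minicircle nanodisc design arithmetic.
#
# A 147 bp minicircle at 0.34 nm/bp rise and 2 nm helix width; PEG
# modification densities for the 21- and 7-modification constructs; and
# the lipid count that fills the ring lumen (two leaflets), giving the
# DNA:lipid stoichiometry used when assembling nanodiscs.
#
# Output: results/05_design.tsv.

library(dlntraj)

d21 <- minicircle_design(147, n_modifications = 21)
d7 <- minicircle_design(147, n_modifications = 7)

tab <- design_table(d21)
print(tab, row.names = FALSE)
message(sprintf("low-PEG construct: %.1f PEG per helical turn",
                peg_density(7, 147)))

g <- minicircle_geometry(d21)
message(sprintf(
  "ring: centerline %.2f nm, outer %d nm, inner %d nm; fill %s lipids",
  g$centerline, g$outer_nm, g$inner_nm,
  lipid_fill(g$inner_nm)$lipid_count))

# characteristic spacing between molecules of each species in one leaflet
# of the simulated patch (comparator for the diffusion displacements)
leaf_area <- pi * 79^2
sp_counts <- c(DMPC = 0.90, DMTAP = 0.09, DMPE = 0.01) * 282
for (sp in names(sp_counts))
  message(sprintf("  %s: ~%.0f per leaflet, spacing ~%.0f A", sp,
                  sp_counts[[sp]],
                  species_spacing(leaf_area, sp_counts[[sp]])))

dir.create("results", showWarnings = FALSE)
write.table(tab, "results/05_design.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("Wrote results/05_design.tsv")
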