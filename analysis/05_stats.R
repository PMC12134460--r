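#!/usr/bin/env Rscript

# Stage 5: statistical comparisons.
#
# Runs the lifestyle ANOVA on per-species overall preservation, the
# lifestyle x pathway-group and organelle-status x pathway-group two-way
# ANOVAs (Type III, sum-to-zero) on per-cell mean lengths, the pathway-group
# length ratios, and the physical-interaction-count summary. Writes
# results/stats/.

library(repairome)

world <- read_world("results/world")
mat <- read.delim("results/orthology/presence_length_matrix.tsv",
                  na.strings = "", stringsAsFactors = FALSE)
by_sp <- read.delim("results/preservation/preservation_by_species.tsv",
                    na.strings = "", stringsAsFactors = FALSE)
dec <- read.delim("results/domains/decomposition.tsv",
                  na.strings = "", stringsAsFactors = FALSE)
out <- "results/stats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

lf <- world$species$lifestyle[match(by_sp$species_id,
                                    world$species$species_id)]
a1 <- one_way_anova(by_sp$mean_preservation, lf)
message(sprintf("preservation ~ lifestyle: F(%d, %d) = %.2f, P = %.3g",
                a1$df[1], a1$df[2], a1$F[1], a1$p[1]))

d_lf <- world$species$lifestyle[match(dec$species_id,
                                      world$species$species_id)]
d_st <- world$species$organelle_status[match(dec$species_id,
                                             world$species$species_id)]
a2 <- two_way_anova(dec$mean_length, d_lf, dec$pathway_group)
i2 <- a2[a2$effect == "A:B", ]
message(sprintf("length ~ lifestyle x group interaction: F(%d, %d) = %.3f, P = %.3g",
                i2$df, a2$df[a2$effect == "residual"], i2$F, i2$p))
a3 <- two_way_anova(dec$mean_length, d_st, dec$pathway_group)
i3 <- a3[a3$effect == "A:B", ]
message(sprintf("length ~ organelle status x group interaction: F(%d, %d) = %.3f, P = %.3g",
                i3$df, a3$df[a3$effect == "residual"], i3$F, i3$p))

presm <- mat[mat$status == "present", ]
grp <- world$catalog$pathway_group[match(presm$anchor_id,
                                         world$catalog$anchor_id)]
means <- tapply(presm$representative_length, grp, mean)
ratios <- group_length_ratios(means[c("DDR", "replication", "metabolic",
                                      "housekeeping")])
message(sprintf("DDR proteins are %.0f%% longer than housekeeping and %.0f%% longer than metabolic proteins",
                ratios$pct_longer[ratios$group_a == "DDR" &
                                  ratios$group_b == "housekeeping"],
                ratios$pct_longer[ratios$group_a == "DDR" &
                                  ratios$group_b == "metabolic"]))

inter <- interaction_count_summary(world$interactions, world$catalog)
message("mean physical interactions per group:")
print(inter)

anovas <- rbind(cbind(analysis = "preservation~lifestyle", a1),
                cbind(analysis = "length~lifestyle*group", a2),
                cbind(analysis = "length~status*group", a3))
write.table(anovas, file.path(out, "anova.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE, na = "")
write.table(ratios, file.path(out, "length_ratios.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, na = "")
write.table(inter, file.path(out, "interaction_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, na = "")
message(sprintf("wrote 3 tables to %s/", out))
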