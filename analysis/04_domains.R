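#!/usr/bin/env Rscript

# Stage 4: domain / interdomain decomposition.
#
# Scores every protein's Pfam hits into merged-interval domain length D,
# interdomain length I = length - D and footprint D / length; summarises
# per (species, pathway-group) cell; and correlates species-level mean
# length, D and I (Spearman). Writes results/domains/.

library(repairome)

world <- read_world("results/world")
mat <- read.delim("results/orthology/presence_length_matrix.tsv",
                  na.strings = "", stringsAsFactors = FALSE)
out <- "results/domains"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

arch <- architecture_table(
  data.frame(protein_id = world$proteins$accession,
             length = world$proteins$length, stringsAsFactors = FALSE),
  world$pfam_hits)
stopifnot(all(arch$domain_length + arch$interdomain_length ==
              arch$protein_length))
message(sprintf("scored %d proteins (%d domain hits)", nrow(arch),
                nrow(world$pfam_hits)))

dec <- group_length_decomposition(arch, mat, world$catalog, world$species)
fp <- tapply(dec$mean_footprint, dec$pathway_group, mean)
dd <- tapply(dec$domain_density_per_100, dec$pathway_group, mean)
message("mean footprint by pathway group (DDR/replication compact, ",
        "housekeeping broad):")
print(round(fp, 3))
message("domains per 100 covered residues (density):")
print(round(dd, 2))

profile <- species_length_profile(arch, mat)
corr <- length_correlations(profile)
message("species-level Spearman correlations:")
print(transform(corr, rho = round(rho, 3), p = signif(p, 3)))

write.table(arch, file.path(out, "architectures.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, na = "")
write.table(dec, file.path(out, "decomposition.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, na = "")
write.table(profile, file.path(out, "species_length_profile.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, na = "")
write.table(corr, file.path(out, "correlations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, na = "")
message(sprintf("wrote 4 tables to %s/", out))
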