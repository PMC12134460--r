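#!/usr/bin/env Rscript

# Stage 3: pathway preservation.
#
# Scores per-(species, pathway) preservation values from the rescued
# presence matrix, summarises them by species, pathway and lifestyle x
# pathway-group cell, counts per-species DDR repertoires, and exports the
# wide presence/length heatmap matrix. Writes results/preservation/.

library(repairome)

world <- read_world("results/world")
mat <- read.delim("results/orthology/presence_length_matrix.tsv",
                  na.strings = "", stringsAsFactors = FALSE)
out <- "results/preservation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pres <- pathway_preservation(mat, world$catalog)
by_sp <- mean_preservation(pres, by = "species", species = world$species)
by_pw <- mean_preservation(pres, by = "pathway")
by_lg <- mean_preservation(pres, by = "lifestyle_group",
                           species = world$species)

lf <- tapply(by_sp$mean_preservation, by_sp$lifestyle, mean)
message("mean overall preservation by lifestyle:")
print(round(lf[c("free_living", "extracellular", "cytoplasmic",
                 "intranuclear")], 3))
top <- by_pw[order(-by_pw$mean_preservation), ][1:3, ]
message("most preserved pathways:")
print(top[c("pathway", "pathway_group", "mean_preservation")])

rep_size <- ddr_repertoire_size(mat, world$catalog)
small <- rep_size[order(rep_size$n_ddr_present), ][1:5, ]
message("smallest DDR repertoires (of ",
        sum(world$catalog$pathway_group == "DDR"), " anchors):")
print(small)

heat <- heatmap_matrix(mat, world$catalog)

for (x in c("pres", "by_sp", "by_pw", "by_lg", "rep_size", "heat")) {
  f <- file.path(out, paste0(switch(x, pres = "preservation",
                                    by_sp = "preservation_by_species",
                                    by_pw = "preservation_by_pathway",
                                    by_lg = "preservation_by_lifestyle_group",
                                    rep_size = "ddr_repertoire",
                                    heat = "heatmap"), ".tsv"))
  write.table(get(x), f, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
}
message(sprintf("wrote 6 tables to %s/", out))
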