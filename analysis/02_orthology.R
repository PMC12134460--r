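#!/usr/bin/env Rscript

# Stage 2: human-anchored orthology.
#
# Parses the world's orthogroup table into the anchor x species
# presence/length matrix, applies the clade-reference bait rescue to
# absences, and audits calling reliability on >95%-conserved groups under
# the binomial failure model. Writes results/orthology/.

library(repairome)

world <- read_world("results/world")
out <- "results/orthology"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fam <- build_family_map(world$orthogroups, world$catalog, "hsap")
message(sprintf("family map: %d/%d anchors found in orthogroups",
                sum(!is.na(fam$orthogroup_id)), nrow(fam)))

mat <- build_presence_matrix(fam, world$orthogroups, world$proteins,
                             world$species)
direct <- sum(mat$status == "present")
mat <- rescue_missing(mat, world$pairs, world$species,
                      world$reference_orthology, world$proteins)
message(sprintf("presence: %d direct, %d rescued via clade-reference baits",
                direct, sum(mat$provenance == "rescued")))

audit <- audit_conserved_groups(mat, threshold = 0.95,
                                failure_prob = 0.045,
                                drop_species = "hsap")
with_abs <- audit[audit$n_absent > 0, ]
message(sprintf(paste0("audit: %d groups >95%% conserved; among those with ",
                       "absences, P(all absences are calling failures) ",
                       "spans %.1f%% to %.1f%%"),
                nrow(audit), 100 * min(with_abs$p_fail),
                100 * max(with_abs$p_fail)))

write.table(mat, file.path(out, "presence_length_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, na = "")
write.table(audit, file.path(out, "audit.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE, na = "")
message(sprintf("wrote %s/presence_length_matrix.tsv and audit.tsv", out))
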