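#' @title Human-anchored orthologue presence and rescue
#'
#' @description
#' Builds the (human anchor x species) presence/length matrix from an
#' orthogroup table, recovers orthologues missed by global clustering by
#' routing through a clade-reference species ("bait rescue"), and audits
#' calling reliability on highly conserved orthologue groups with a binomial
#' failure model.
#'
#' @name orthology
NULL

#' Map human anchor proteins to orthogroups
#'
#' Each anchor is mapped to the orthogroup containing it in the human
#' column; anchors absent from every orthogroup map to `NA`. Two anchors may
#' legitimately share an orthogroup (co-orthology); each then receives that
#' orthogroup's members independently downstream.
#'
#' @param orthogroups Long-format orthogroup table ([read_orthogroups()]).
#' @param catalog Pathway catalogue ([read_pathway_catalog()]).
#' @param human_species_id The species id whose accessions are the anchors.
#' @return data.frame `anchor_id`, `orthogroup_id` (`NA` when unassigned).
#' @export
build_family_map <- function(orthogroups, catalog, human_species_id) {
  hs <- orthogroups[orthogroups$species_id == human_species_id, , drop = FALSE]
  idx <- match(catalog$anchor_id, hs$accession)
  data.frame(anchor_id = catalog$anchor_id,
             orthogroup_id = hs$orthogroup_id[idx],
             stringsAsFactors = FALSE)
}

#' Build the presence/length matrix
#'
#' One row per (anchor, species). A cell is `present` when the anchor's
#' orthogroup has members in that species; the representative length is the
#' maximum over in-paralogues (`rep_rule = "max"`, the default, matching the
#' longest-protein analyses; `"mean"` is available) and `n_copies` records
#' the member count. Absences in species flagged `excluded_absences` become
#' `excluded`. Provenance is `direct` for presences from the orthogroup
#' table and `none` otherwise; [rescue_missing()] upgrades recovered
#' absences to `rescued`.
#'
#' @param family_map Output of [build_family_map()].
#' @param orthogroups Long-format orthogroup table.
#' @param proteins Protein table with `species_id`, `accession` (or
#'   `protein_id`), `length`; every accession in `orthogroups` must resolve.
#' @param species Species metadata ([read_species_metadata()]).
#' @param rep_rule `"max"` (default) or `"mean"` representative length.
#' @return data.frame `anchor_id`, `species_id`, `status`
#'   (present/absent/excluded), `representative_length`,
#'   `representative_accession` (longest member), `n_copies`, `provenance`
#'   (direct/none).
#' @export
build_presence_matrix <- function(family_map, orthogroups, proteins, species,
                                  rep_rule = c("max", "mean")) {
  rep_rule <- match.arg(rep_rule)
  if (!"accession" %in% names(proteins) && "protein_id" %in% names(proteins))
    proteins$accession <- proteins$protein_id
  pkey <- paste(orthogroups$species_id, orthogroups$accession)
  plen <- proteins$length[match(pkey,
                                paste(proteins$species_id,
                                      proteins$accession))]
  if (anyNA(plen)) {
    i <- which(is.na(plen))[1]
    abort("accession %s of species %s is not resolvable to a protein record",
          orthogroups$accession[i], orthogroups$species_id[i])
  }
  # per (orthogroup, species): n members, max length + its accession, mean
  cell <- paste(orthogroups$orthogroup_id, orthogroups$species_id, sep = "\r")
  o <- order(cell, plen)
  last <- !duplicated(cell[o], fromLast = TRUE)
  stats_df <- data.frame(key = cell[o][last],
                         max_len = plen[o][last],
                         max_acc = orthogroups$accession[o][last],
                         stringsAsFactors = FALSE)
  stats_df$n <- as.integer(table(cell)[stats_df$key])
  stats_df$mean_len <- as.numeric(tapply(plen, cell, mean)[stats_df$key])

  grid <- expand.grid(anchor_id = family_map$anchor_id,
                      species_id = species$species_id,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  og <- family_map$orthogroup_id[match(grid$anchor_id, family_map$anchor_id)]
  idx <- match(paste(og, grid$species_id, sep = "\r"), stats_df$key)
  present <- !is.na(idx)
  excluded <- species$excluded_absences[match(grid$species_id,
                                              species$species_id)]
  status <- ifelse(present, "present",
                   ifelse(excluded, "excluded", "absent"))
  rep_len <- ifelse(present,
                    if (rep_rule == "max") stats_df$max_len[idx] else
                      stats_df$mean_len[idx],
                    NA_real_)
  out <- data.frame(anchor_id = grid$anchor_id,
                    species_id = grid$species_id,
                    status = status,
                    representative_length = rep_len,
                    representative_accession = ifelse(present,
                                                      stats_df$max_acc[idx],
                                                      NA_character_),
                    n_copies = ifelse(present, stats_df$n[idx], 0L),
                    provenance = ifelse(present, "direct", "none"),
                    stringsAsFactors = FALSE)
  attr(out, "rep_rule") <- rep_rule
  out
}

#' Rescue orthologues missed by global clustering
#'
#' For each `absent` (anchor, species) cell: if the anchor has a confirmed
#' reference orthologue in the species' clade-reference proteome, that
#' reference accession is used as bait in the reference-vs-query pairing
#' rows; when the bait co-occurs with at least one accession of the query
#' species, the cell becomes `present` with provenance `rescued`,
#' representative length the maximum over the paired accessions. Present and
#' excluded cells are never modified; the operation is idempotent.
#'
#' @param matrix Presence matrix from [build_presence_matrix()].
#' @param pairs Expanded pairing rows ([read_pairwise_orthologs()] layout,
#'   possibly several files row-bound; either orientation of the
#'   reference/query pair is accepted).
#' @param species Species metadata; every species must declare a
#'   `clade_reference`.
#' @param reference_orthology Confirmed anchor-to-reference-accession table
#'   ([read_reference_orthology()]).
#' @param proteins Protein table used to resolve paired accession lengths.
#' @param rep_rule `"max"` (default) or `"mean"` representative length for
#'   rescued cells.
#' @return The matrix with rescued cells upgraded.
#' @export
rescue_missing <- function(matrix, pairs, species, reference_orthology,
                           proteins,
                           rep_rule = attr(matrix, "rep_rule") %||% "max") {
  if (!"accession" %in% names(proteins) && "protein_id" %in% names(proteins))
    proteins$accession <- proteins$protein_id
  ref_of <- species$clade_reference
  names(ref_of) <- species$species_id
  if (any(is.na(ref_of) | !nzchar(ref_of)))
    abort("species without a declared clade_reference: %s",
          paste(names(ref_of)[is.na(ref_of) | !nzchar(ref_of)],
                collapse = ", "))
  absent <- which(matrix$status == "absent")
  if (length(absent) == 0L || is.null(pairs) || nrow(pairs) == 0L)
    return(matrix)
  # normalise pairing rows to (ref_species, bait, query_species, query_gene)
  norm <- rbind(
    data.frame(ref_species = pairs$species_a, bait = pairs$gene_a,
               query_species = pairs$species_b, query_gene = pairs$gene_b,
               stringsAsFactors = FALSE),
    data.frame(ref_species = pairs$species_b, bait = pairs$gene_b,
               query_species = pairs$species_a, query_gene = pairs$gene_a,
               stringsAsFactors = FALSE))
  cand <- data.frame(i = absent,
                     anchor_id = matrix$anchor_id[absent],
                     species_id = matrix$species_id[absent],
                     stringsAsFactors = FALSE)
  cand$ref <- unname(ref_of[cand$species_id])
  bait <- reference_orthology$reference_accession[
    match(paste(cand$ref, cand$anchor_id),
          paste(reference_orthology$reference_species,
                reference_orthology$anchor_id))]
  cand <- cand[!is.na(bait), , drop = FALSE]
  cand$bait <- bait[!is.na(bait)]
  if (nrow(cand) == 0L) return(matrix)
  hit <- merge(cand, norm,
               by.x = c("ref", "bait", "species_id"),
               by.y = c("ref_species", "bait", "query_species"))
  if (nrow(hit) == 0L) return(matrix)
  hit$len <- proteins$length[match(paste(hit$species_id, hit$query_gene),
                                   paste(proteins$species_id,
                                         proteins$accession))]
  if (anyNA(hit$len)) {
    j <- which(is.na(hit$len))[1]
    abort("paired accession %s of species %s is not resolvable",
          hit$query_gene[j], hit$species_id[j])
  }
  hit <- hit[!duplicated(hit[c("i", "query_gene")]), , drop = FALSE]
  o <- order(hit$i, hit$len)
  last <- !duplicated(hit$i[o], fromLast = TRUE)
  i <- hit$i[o][last]
  matrix$status[i] <- "present"
  matrix$provenance[i] <- "rescued"
  matrix$representative_accession[i] <- hit$query_gene[o][last]
  matrix$representative_length[i] <- if (rep_rule == "mean")
    as.numeric(tapply(hit$len, hit$i, mean)[as.character(i)]) else
    hit$len[o][last]
  matrix$n_copies[i] <- as.integer(table(hit$i)[as.character(i)])
  matrix
}

#' Tail probability of the calling-failure null model
#'
#' `P(X >= k)` with `X ~ Binomial(n, f)`: the probability of observing at
#' least the recorded number of missing orthologues purely from independent
#' per-species calling failures at rate `f`. Vectorised over `n`, `k`, `f`.
#'
#' @param n Number of assessable species.
#' @param k Observed absences, `0 <= k <= n`.
#' @param f Per-species calling failure probability in `[0, 1]`.
#' @return Numeric tail probabilities (`k = 0` gives 1; `f = 0, k >= 1`
#'   gives 0).
#' @export
calling_failure_tail <- function(n, k, f) {
  if (any(f < 0 | f > 1)) abort("f must lie in [0, 1]")
  if (any(k < 0 | k > n)) abort("k must lie in [0, n]")
  stats::pbinom(k - 1, n, f, lower.tail = FALSE)
}

#' Audit orthologue-calling reliability on conserved groups
#'
#' Selects anchors present in more than `threshold` of assessable species
#' (excluded cells, and any species listed in `drop_species`, are removed
#' from numerator and denominator) and asks how probable the observed
#' absences would be if every absence were an independent calling failure:
#' `p_fail = P(X >= k)` with `X ~ Binomial(n, f)`, `k` the observed absences
#' among `n` assessable species. `k = 0` gives `p_fail = 1`; `f = 0` with
#' `k >= 1` gives 0.
#'
#' @param matrix Presence matrix (after rescue, typically).
#' @param threshold Conservation threshold in (0, 1]; default 0.95.
#' @param failure_prob Assumed per-species calling failure probability `f`
#'   (default 0.045, one minus the lower bound of audited calling coverage).
#' @param drop_species Species ids excluded from assessment (the anchor
#'   species itself, typically).
#' @return data.frame, one row per audited anchor: `anchor_id`, `n_species`,
#'   `n_absent`, `conservation`, `failure_prob`, `p_fail`.
#' @export
audit_conserved_groups <- function(matrix, threshold = 0.95,
                                   failure_prob = 0.045,
                                   drop_species = character()) {
  if (!(threshold > 0 && threshold <= 1))
    abort("threshold must lie in (0, 1]")
  if (failure_prob < 0 || failure_prob > 1)
    abort("failure_prob must lie in [0, 1]")
  m <- matrix[matrix$status != "excluded" &
              !(matrix$species_id %in% drop_species), , drop = FALSE]
  f <- factor(m$anchor_id)
  n <- as.integer(table(f))
  k <- as.integer(tapply(m$status == "absent", f, sum))
  cons <- (n - k) / n
  keep <- n > 0L & cons > threshold
  out <- data.frame(anchor_id = levels(f)[keep],
                    n_species = n[keep], n_absent = k[keep],
                    conservation = cons[keep],
                    failure_prob = rep(failure_prob, sum(keep)),
                    p_fail = calling_failure_tail(n[keep], k[keep],
                                                  failure_prob),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
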