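#' @title Synthetic analysis worlds with known ground truth
#'
#' @description
#' Generates complete synthetic comparative-genomics worlds — species
#' metadata, per-species proteomes, a pathway catalogue, orthogroup and
#' pairwise-ortholog tables, Pfam-style domain tables and interaction
#' counts — from a seeded configuration, together with the ground truth that
#' produced them. Every emitted file passes its reader in the I/O module,
#' and every downstream stage can be checked against the truth.
#'
#' The world emulates the design of a multi-species DDR survey: a human
#' anchor species; lifestyle-graded orthologue loss (retention declining
#' from free-living to intranuclear, and DDR lost before replication);
#' log-normal protein lengths with pathway-group median multipliers (DDR and
#' replication 1.84x housekeeping by default); group-specific domain
#' footprints and counts; planted orthogroup-clustering misses recoverable
#' through clade-reference pairing files; and optionally one species with a
#' deliberately truncated proteome whose absences are flagged excluded.
#'
#' @name synthetic_data
NULL

default_pathway_sizes <- function() {
  list(
    DDR = c(checkpoint_factors = 90, homologous_recombination = 60,
            nonhomologous_end_joining = 30, mismatch_repair = 25,
            base_excision_repair = 40, nucleotide_excision_repair = 45,
            translesion_synthesis = 30, fanconi_anaemia = 25,
            direct_reversal = 10, chromatin_remodelling = 50,
            ddr_ubiquitin_signalling = 21, nucleotide_pool_modulation = 6),
    replication = c(dna_replication = 35),
    metabolic = c(central_carbon_metabolism = 20,
                  amino_acid_metabolism = 18),
    housekeeping = c(housekeeping_core = 21))
}

default_retention <- function() {
  m <- rbind(free_living   = c(0.90, 0.98, 0.92, 0.96),
             extracellular = c(0.75, 0.92, 0.80, 0.88),
             cytoplasmic   = c(0.60, 0.85, 0.70, 0.80),
             intranuclear  = c(0.35, 0.75, 0.50, 0.68))
  colnames(m) <- PATHWAY_GROUPS
  m
}

#' Configuration for a synthetic world
#'
#' Defaults reproduce the design of the study the pipeline emulates: 68
#' species (the human anchor species plus 27 further free-living, 20
#' extracellular, 16 cytoplasmic and 4 intranuclear), a catalogue of 432 DDR
#' + 35 replication + 38 metabolic + 21 housekeeping anchors, log-normal
#' lengths whose medians make DDR and replication proteins 1.84x (and
#' metabolic proteins 1.84/1.24x) housekeeping length, retention
#' probabilities that decline monotonically from free-living to intranuclear
#' with replication >= housekeeping >= metabolic >= DDR, domain footprints of
#' 0.40/0.45/0.55/0.60 with mean hit counts 4/4/2/2 (DDR packs more domains
#' into a smaller footprint), a clustering-miss rate of 0.045 (one minus the
#' lower bound of the audited calling coverage), and mean physical
#' interaction counts of 15 (DDR) vs 6 (housekeeping).
#'
#' @param seed Master seed; all per-species and per-file substreams are
#'   derived deterministically from it, so the world is bit-for-bit
#'   reproducible and adding a species does not reshuffle the others.
#' @param n_species Named integer vector of species counts per lifestyle
#'   (the human species counts toward `free_living`).
#' @param pathway_sizes Named list (per pathway group) of named integer
#'   vectors of per-pathway anchor counts.
#' @param housekeeping_median Median housekeeping protein length (residues).
#' @param log_sd Log-scale standard deviation of protein lengths.
#' @param multipliers Median length multipliers per pathway group.
#' @param retention Lifestyle x pathway-group retention probability matrix.
#' @param footprint Mean domain coverage fraction per pathway group.
#' @param domain_count Mean raw Pfam hit count per pathway group.
#' @param miss_rate Probability `q` that a truly present orthologue is
#'   omitted from the orthogroup table but kept in the clade-reference
#'   pairing file (a planted, rescuable clustering failure).
#' @param paralog_prob Probability that a present orthologue has a second
#'   in-paralogue copy.
#' @param dup_hit_frac Fraction of domain hits duplicated as nested
#'   overlapping hits (exercises interval merging without changing
#'   coverage).
#' @param interaction_means Mean physical-interaction count per pathway
#'   group.
#' @param include_excluded_species Flag one extracellular species as having
#'   a truncated proteome with `excluded_absences = TRUE`.
#' @param truncation_frac Fraction of the excluded species' truly present
#'   orthologues dropped by the truncation.
#' @param n_clades Number of clades; each clade gets a free-living reference
#'   species (the human clade's reference is the human species itself).
#' @param human_species_id Identifier of the human anchor species.
#' @return A validated `world_config` list.
#' @export
world_config <- function(seed = 1L,
                         n_species = c(free_living = 28, extracellular = 20,
                                       cytoplasmic = 16, intranuclear = 4),
                         pathway_sizes = default_pathway_sizes(),
                         housekeeping_median = 400,
                         log_sd = 0.35,
                         multipliers = c(DDR = 1.84, replication = 1.84,
                                         metabolic = 1.84 / 1.24,
                                         housekeeping = 1),
                         retention = default_retention(),
                         footprint = c(DDR = 0.40, replication = 0.45,
                                       metabolic = 0.55, housekeeping = 0.60),
                         domain_count = c(DDR = 4, replication = 4,
                                          metabolic = 2, housekeeping = 2),
                         miss_rate = 0.045,
                         paralog_prob = 0.05,
                         dup_hit_frac = 0.10,
                         interaction_means = c(DDR = 15, replication = 12,
                                               metabolic = 8,
                                               housekeeping = 6),
                         include_excluded_species = TRUE,
                         truncation_frac = 0.4,
                         n_clades = 6,
                         human_species_id = "hsap") {
  stopifnot(all(LIFESTYLES %in% names(n_species)),
            all(n_species >= 0), n_species["free_living"] >= 1)
  stopifnot(setequal(names(pathway_sizes), PATHWAY_GROUPS))
  stopifnot(all(PATHWAY_GROUPS %in% names(multipliers)),
            all(multipliers > 0))
  stopifnot(is.matrix(retention),
            setequal(rownames(retention), LIFESTYLES),
            setequal(colnames(retention), PATHWAY_GROUPS),
            all(retention >= 0 & retention <= 1))
  for (p in c(miss_rate, paralog_prob, dup_hit_frac, truncation_frac))
    stopifnot(p >= 0, p <= 1)
  stopifnot(all(footprint > 0))
  if (any(footprint > 0.9))
    abort("footprint target(s) above 0.9 demand more domain coverage than protein length allows")
  stopifnot(all(domain_count >= 1), housekeeping_median > 0, log_sd > 0,
            n_clades >= 1)
  cfg <- list(seed = as.integer(seed), n_species = n_species,
              pathway_sizes = pathway_sizes,
              housekeeping_median = housekeeping_median, log_sd = log_sd,
              multipliers = multipliers[PATHWAY_GROUPS],
              retention = retention[LIFESTYLES, PATHWAY_GROUPS],
              footprint = footprint[PATHWAY_GROUPS],
              domain_count = domain_count[PATHWAY_GROUPS],
              miss_rate = miss_rate, paralog_prob = paralog_prob,
              dup_hit_frac = dup_hit_frac,
              interaction_means = interaction_means[PATHWAY_GROUPS],
              include_excluded_species = include_excluded_species,
              truncation_frac = truncation_frac,
              n_clades = as.integer(n_clades),
              human_species_id = human_species_id)
  class(cfg) <- "world_config"
  cfg
}

CLADE_NAMES <- c("metazoa", "fungi", "stramenopila", "alveolata",
                 "excavata", "amoebozoa")

make_species_table <- function(cfg) {
  counts <- cfg$n_species[LIFESTYLES]
  lifestyles <- rep(LIFESTYLES, counts)
  n <- length(lifestyles)
  ids <- sprintf("sp%02d", seq_len(n))
  ids[1] <- cfg$human_species_id        # human is the first free-living species
  display <- sprintf("Synthosoma %s", ids)
  display[1] <- "Homo sapiens (anchor)"
  # organelle status: all intranuclear plus the first 4 cytoplasmic species
  # lack ATP-producing mitochondria
  status <- rep("atp_mito_or_plastid", n)
  cyt <- which(lifestyles == "cytoplasmic")
  status[utils::head(cyt, 4L)] <- "no_atp_mito"
  status[lifestyles == "intranuclear"] <- "no_atp_mito"
  clade_names <- if (cfg$n_clades <= length(CLADE_NAMES))
    CLADE_NAMES[seq_len(cfg$n_clades)] else
    sprintf("clade%02d", seq_len(cfg$n_clades))
  # round-robin within each lifestyle so every clade gets free-living members
  clade <- character(n)
  for (lf in LIFESTYLES) {
    i <- which(lifestyles == lf)
    clade[i] <- clade_names[(seq_along(i) - 1L) %% cfg$n_clades + 1L]
  }
  clade[1] <- clade_names[1]
  # reference = first free-living species of each clade (human for its own)
  ref_of <- vapply(clade_names, function(cl) {
    i <- which(clade == cl & lifestyles == "free_living")
    if (length(i) == 0L)
      abort("clade %s has no free-living species to act as reference", cl)
    ids[i[1]]
  }, character(1))
  excluded <- rep(FALSE, n)
  if (cfg$include_excluded_species) {
    ex <- which(lifestyles == "extracellular")
    if (length(ex) > 0L) excluded[ex[length(ex)]] <- TRUE
  }
  data.frame(species_id = ids, display_name = display,
             lifestyle = lifestyles, organelle_status = status,
             clade = clade, clade_reference = unname(ref_of[clade]),
             excluded_absences = excluded, stringsAsFactors = FALSE)
}

make_catalog <- function(cfg) {
  rows <- list()
  i <- 0L
  for (grp in PATHWAY_GROUPS) {
    sizes <- cfg$pathway_sizes[[grp]]
    for (pw in names(sizes)) {
      k <- sizes[[pw]]
      rows[[length(rows) + 1L]] <-
        data.frame(anchor_id = sprintf("HSP%05d", i + seq_len(k)),
                   pathway = pw, pathway_group = grp,
                   stringsAsFactors = FALSE)
      i <- i + k
    }
  }
  do.call(rbind, rows)
}

# grouped sum broadcast back to rows; g must be sorted
gsum_rep <- function(x, g) {
  r <- rle(g)
  rep(as.numeric(rowsum(x, g)), r$lengths)
}

# Place k non-adjacent domain segments covering round(cov * len) residues of
# each protein; returns pfam-hit rows (including nested duplicate hits).
place_domains <- function(acc, len, grp, cfg) {
  n <- length(acc)
  if (n == 0L)
    return(data.frame(protein_id = character(0), alignment_start = integer(0),
                      alignment_end = integer(0), envelope_start = integer(0),
                      envelope_end = integer(0), pfam_accession = character(0),
                      domain_name = character(0), bit_score = numeric(0),
                      e_value = numeric(0), stringsAsFactors = FALSE))
  cov <- cfg$footprint[grp]
  dtot <- pmax(5L, as.integer(round(cov * len)))
  if (any(dtot >= len))
    abort("domain coverage target leaves no interdomain residues for protein %s",
          acc[which(dtot >= len)[1]])
  k <- pmax(1L, stats::rpois(n, cfg$domain_count[grp]))
  k <- pmax(1L, pmin(k, dtot %/% 5L, len - dtot))
  pid <- rep(seq_len(n), k)
  # split dtot into k parts of >= 5 residues
  w <- stats::runif(length(pid))
  parts <- 5L + as.integer(floor((rep(dtot, k) - 5L * rep(k, k)) *
                                 w / gsum_rep(w, pid)))
  first <- !duplicated(pid)
  parts[first] <- parts[first] + (dtot - as.integer(rowsum(parts, pid)))
  # split the uncovered len - dtot residues into k + 1 gaps; internal gaps
  # keep >= 1 uncovered residue so segments are never adjacent
  gid <- rep(seq_len(n), k + 1L)
  slot <- sequence(k + 1L)
  kk <- rep(k, k + 1L)
  base <- as.integer(slot > 1L & slot <= kk)
  u <- stats::runif(length(gid))
  extra <- rep(len - dtot, k + 1L) - rep(k - 1L, k + 1L)
  gaps <- base + as.integer(floor(extra * u / gsum_rep(u, gid)))
  lastslot <- slot == kk + 1L
  gaps[lastslot] <- gaps[lastslot] +
    ((len - dtot) - as.integer(rowsum(gaps, gid)))
  gap_before <- gaps[slot <= kk]           # gaps 1..k, aligned with parts
  start <- as.integer(grouped_cumsum(gap_before, pid)) +
    as.integer(grouped_cumsum(parts, pid)) - parts + 1L
  end <- start + parts - 1L
  hits <- data.frame(protein_id = acc[pid], envelope_start = start,
                     envelope_end = end, stringsAsFactors = FALSE)
  # nested duplicates: overlapping hits that leave coverage unchanged
  dup <- which(stats::runif(nrow(hits)) < cfg$dup_hit_frac & parts >= 7L)
  if (length(dup) > 0L) {
    d <- hits[dup, , drop = FALSE]
    d$envelope_start <- d$envelope_start + 2L
    d$envelope_end <- d$envelope_end - 2L
    hits <- rbind(hits, d)
    o <- order(match(hits$protein_id, acc), hits$envelope_start)
    hits <- hits[o, , drop = FALSE]
  }
  m <- nrow(hits)
  wdt <- hits$envelope_end - hits$envelope_start + 1L
  trim <- as.integer(wdt >= 5L)
  fam <- sample.int(400L, m, replace = TRUE)
  hits$alignment_start <- hits$envelope_start + trim
  hits$alignment_end <- hits$envelope_end - trim
  hits$pfam_accession <- sprintf("PF%05d.1", fam)
  hits$domain_name <- sprintf("SynDom_%03d", fam)
  hits$bit_score <- round(stats::runif(m, 30, 300), 1)
  hits$e_value <- 10^stats::runif(m, -30, -5)
  rownames(hits) <- NULL
  hits[c("protein_id", "alignment_start", "alignment_end", "envelope_start",
         "envelope_end", "pfam_accession", "domain_name", "bit_score",
         "e_value")]
}

#' Generate a synthetic world
#'
#' Draws presence, copy number, lengths, domain architectures, planted
#' clustering misses and interaction counts from the configured models, and
#' assembles every table the pipeline ingests, together with the ground
#' truth. Use [write_world()] to materialise the world as files in the
#' external formats and [truth_summary()] for analytic expectations.
#'
#' @param cfg A [world_config()].
#' @return An object of class `ddr_world`: a list with `config`, `species`,
#'   `catalog`, `family` (anchor to orthogroup id), `proteins`,
#'   `orthogroups` (long format, planted misses withheld), `pairs` (expanded
#'   clade-reference pairing rows), `reference_orthology`, `pfam_hits`,
#'   `interactions` and `truth` (per anchor x species: `present`,
#'   `n_copies`, `length`, `representative_accession`, `missed`,
#'   `rescuable`).
#' @export
generate_world <- function(cfg = world_config()) {
  stopifnot(inherits(cfg, "world_config"))
  species <- make_species_table(cfg)
  catalog <- make_catalog(cfg)
  n_anchor <- nrow(catalog)
  family <- data.frame(anchor_id = catalog$anchor_id,
                       orthogroup_id = sprintf("OG%07d", seq_len(n_anchor)),
                       stringsAsFactors = FALSE)
  medians <- cfg$housekeeping_median * cfg$multipliers[catalog$pathway_group]
  ref_ids <- unique(species$clade_reference)
  human <- cfg$human_species_id

  entries <- vector("list", nrow(species))
  proteins <- vector("list", nrow(species))
  hits <- vector("list", nrow(species))
  for (si in seq_len(nrow(species))) {
    sp <- species$species_id[si]
    lf <- species$lifestyle[si]
    is_human <- sp == human
    ent <- with_seed(seed_for(cfg$seed, paste0("presence/", sp)), {
      p <- cfg$retention[lf, catalog$pathway_group]
      present <- if (is_human) rep(TRUE, n_anchor) else
        stats::runif(n_anchor) < p
      if (species$excluded_absences[si])
        present <- present & stats::runif(n_anchor) >= cfg$truncation_frac
      n_copies <- ifelse(present,
                         1L + stats::rbinom(n_anchor, 1L, cfg$paralog_prob),
                         0L)
      if (is_human) n_copies <- ifelse(present, 1L, 0L)
      cp_anchor <- rep(seq_len(n_anchor), n_copies)
      cp_len <- pmax(50L, as.integer(round(stats::rlnorm(
        length(cp_anchor), meanlog = log(medians[cp_anchor]),
        sdlog = cfg$log_sd))))
      missed <- rep(FALSE, n_anchor)
      if (!is_human && !(sp %in% ref_ids) && !species$excluded_absences[si])
        missed <- present & stats::runif(n_anchor) < cfg$miss_rate
      list(present = present, n_copies = n_copies, cp_anchor = cp_anchor,
           cp_len = cp_len, missed = missed)
    })
    acc <- if (is_human) catalog$anchor_id[ent$cp_anchor] else
      sprintf("%s_p%05d", sp, seq_along(ent$cp_anchor))
    prot <- data.frame(species_id = sp, accession = acc,
                       anchor_id = catalog$anchor_id[ent$cp_anchor],
                       length = ent$cp_len, stringsAsFactors = FALSE)
    proteins[[si]] <- prot
    # representative = longest in-paralogue
    rep_len <- rep(NA_integer_, n_anchor)
    rep_acc <- rep(NA_character_, n_anchor)
    if (nrow(prot) > 0L) {
      o <- order(ent$cp_anchor, ent$cp_len)   # last per anchor = max length
      lastd <- !duplicated(ent$cp_anchor[o], fromLast = TRUE)
      ai <- ent$cp_anchor[o][lastd]
      rep_len[ai] <- ent$cp_len[o][lastd]
      rep_acc[ai] <- acc[o][lastd]
    }
    entries[[si]] <- data.frame(
      anchor_id = catalog$anchor_id, species_id = sp,
      present = ent$present, n_copies = ent$n_copies,
      length = rep_len, representative_accession = rep_acc,
      missed = ent$missed, stringsAsFactors = FALSE)
    hits[[si]] <- with_seed(seed_for(cfg$seed, paste0("domains/", sp)),
      place_domains(prot$accession, prot$length,
                    catalog$pathway_group[match(prot$anchor_id,
                                                catalog$anchor_id)], cfg))
  }
  truth <- do.call(rbind, entries)
  proteins <- do.call(rbind, proteins)
  pfam_hits <- do.call(rbind, hits)
  rownames(truth) <- rownames(proteins) <- rownames(pfam_hits) <- NULL

  # orthogroup table: planted misses withheld
  og_of <- family$orthogroup_id
  names(og_of) <- family$anchor_id
  miss_key <- paste(truth$anchor_id, truth$species_id)[truth$missed]
  keep <- !(paste(proteins$anchor_id, proteins$species_id) %in% miss_key)
  orthogroups <- data.frame(
    orthogroup_id = unname(og_of[proteins$anchor_id[keep]]),
    species_id = proteins$species_id[keep],
    accession = proteins$accession[keep], stringsAsFactors = FALSE)
  attr(orthogroups, "species") <- species$species_id

  # clade-reference pairing rows: every orthogroup with members in both the
  # reference and the query (misses included - the pairwise analysis found
  # them even though the global clustering did not)
  ref_present <- truth[truth$species_id %in% ref_ids & truth$present,
                       c("anchor_id", "species_id")]
  pair_list <- list()
  for (si in which(!(species$species_id %in% ref_ids))) {
    sp <- species$species_id[si]
    ref <- species$clade_reference[si]
    both <- intersect(
      truth$anchor_id[truth$species_id == sp & truth$present],
      ref_present$anchor_id[ref_present$species_id == ref])
    if (length(both) == 0L) next
    pa <- proteins[proteins$species_id == ref &
                   proteins$anchor_id %in% both, c("anchor_id", "accession")]
    pb <- proteins[proteins$species_id == sp &
                   proteins$anchor_id %in% both, c("anchor_id", "accession")]
    m <- merge(pa, pb, by = "anchor_id", suffixes = c("_a", "_b"))
    pair_list[[length(pair_list) + 1L]] <- data.frame(
      orthogroup_id = unname(og_of[m$anchor_id]),
      species_a = ref, species_b = sp,
      gene_a = m$accession_a, gene_b = m$accession_b,
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(pair_list) > 0L) do.call(rbind, pair_list) else
    data.frame(orthogroup_id = character(0), species_a = character(0),
               species_b = character(0), gene_a = character(0),
               gene_b = character(0), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL

  # reference orthology: confirmed reference orthologue per (reference, anchor)
  ro <- truth[truth$species_id %in% ref_ids & truth$present,
              c("species_id", "anchor_id", "representative_accession")]
  reference_orthology <- data.frame(reference_species = ro$species_id,
                                    anchor_id = ro$anchor_id,
                                    reference_accession =
                                      ro$representative_accession,
                                    stringsAsFactors = FALSE)
  rownames(reference_orthology) <- NULL

  interactions <- with_seed(seed_for(cfg$seed, "interactions"), data.frame(
    protein_id = catalog$anchor_id,
    physical_interaction_count =
      stats::rpois(n_anchor, cfg$interaction_means[catalog$pathway_group]),
    stringsAsFactors = FALSE))

  # rescuable = planted miss whose clade reference carries the anchor
  ref_of <- species$clade_reference[match(truth$species_id,
                                          species$species_id)]
  ref_has <- paste(truth$anchor_id, ref_of) %in%
    paste(ref_present$anchor_id, ref_present$species_id)
  truth$rescuable <- truth$missed & ref_has

  structure(list(config = cfg, species = species, catalog = catalog,
                 family = family, proteins = proteins,
                 orthogroups = orthogroups, pairs = pairs,
                 reference_orthology = reference_orthology,
                 pfam_hits = pfam_hits, interactions = interactions,
                 truth = truth),
            class = "ddr_world")
}

#' @export
print.ddr_world <- function(x, ...) {
  cat(sprintf(paste0("<ddr_world> %d species, %d anchors, %d proteins, ",
                     "%d domain hits, %d planted misses (seed %d)\n"),
              nrow(x$species), nrow(x$catalog), nrow(x$proteins),
              nrow(x$pfam_hits), sum(x$truth$missed), x$config$seed))
  invisible(x)
}

random_aa_sequences <- function(lengths) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  res <- sample(aa, sum(lengths), replace = TRUE)
  grp <- rep(seq_along(lengths), lengths)
  vapply(split(res, grp), paste, character(1), collapse = "")
}

#' Write a synthetic world to disk
#'
#' Materialises every table of a [generate_world()] result in the external
#' formats the readers in the I/O module expect: `species.tsv`,
#' `pathway_catalog.tsv`, `Orthogroups.tsv`, `pairs/<ref>__<query>.tsv`,
#' `proteomes/<species>.fasta` (sequences drawn from a per-species
#' substream), `pfam_hits.txt`, `reference_orthology.tsv`,
#' `interaction_counts.tsv` and `ground_truth.tsv` (the synthetic truth).
#'
#' @param world A `ddr_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "ddr_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_species_metadata(world$species, file.path(dir, "species.tsv"))
  write_pathway_catalog(world$catalog, file.path(dir, "pathway_catalog.tsv"))
  write_orthogroups(world$orthogroups, file.path(dir, "Orthogroups.tsv"),
                    species_list = world$species$species_id)
  write_reference_orthology(world$reference_orthology,
                            file.path(dir, "reference_orthology.tsv"))
  write_interaction_counts(world$interactions,
                           file.path(dir, "interaction_counts.tsv"))
  write_pfam_hits(world$pfam_hits, file.path(dir, "pfam_hits.txt"))
  key <- paste(world$pairs$species_a, world$pairs$species_b, sep = "__")
  for (k in unique(key))
    write_pairwise_orthologs(world$pairs[key == k, , drop = FALSE],
                             file.path(dir, "pairs", paste0(k, ".tsv")))
  for (sp in world$species$species_id) {
    prot <- world$proteins[world$proteins$species_id == sp, , drop = FALSE]
    prot$protein_id <- prot$accession
    prot$sequence <- with_seed(seed_for(world$config$seed,
                                        paste0("sequences/", sp)),
                               random_aa_sequences(prot$length))
    write_protein_fasta(prot, file.path(dir, "proteomes",
                                        paste0(sp, ".fasta")))
  }
  write_tsv_strict(world$truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}

#' Read a world directory back into pipeline inputs
#'
#' @param dir Directory written by [write_world()] (or assembled by hand in
#'   the same layout).
#' @return A list with `species`, `catalog`, `proteins`, `orthogroups`,
#'   `pairs`, `reference_orthology`, `pfam_hits`, `interactions`, plus
#'   `truth` when `ground_truth.tsv` is present.
#' @export
read_world <- function(dir) {
  species <- read_species_metadata(file.path(dir, "species.tsv"))
  catalog <- read_pathway_catalog(file.path(dir, "pathway_catalog.tsv"))
  orthogroups <- read_orthogroups(file.path(dir, "Orthogroups.tsv"),
                                  species$species_id)
  prot <- lapply(species$species_id, function(sp)
    read_protein_fasta(file.path(dir, "proteomes", paste0(sp, ".fasta")), sp))
  proteins <- do.call(rbind, prot)
  proteins$sequence <- NULL
  proteins$accession <- proteins$protein_id
  pair_files <- list.files(file.path(dir, "pairs"), full.names = TRUE)
  pairs <- do.call(rbind, lapply(pair_files, read_pairwise_orthologs))
  out <- list(species = species, catalog = catalog, proteins = proteins,
              orthogroups = orthogroups, pairs = pairs,
              reference_orthology =
                read_reference_orthology(file.path(dir,
                                                   "reference_orthology.tsv")),
              pfam_hits = read_pfam_hits(file.path(dir, "pfam_hits.txt")),
              interactions =
                read_interaction_counts(file.path(dir,
                                                  "interaction_counts.tsv")))
  gt <- file.path(dir, "ground_truth.tsv")
  if (file.exists(gt)) out$truth <- read_tsv_strict(gt)
  out
}

#' Analytic expectations for a synthetic world
#'
#' @param world A `ddr_world`.
#' @return List with `expected_preservation` (configured lifestyle x
#'   pathway-group retention), `empirical_presence` (realised per-cell truth
#'   presence fractions), `expected_length_ratio` (pairwise median-length
#'   ratios implied by the configured multipliers), `expected_footprint`,
#'   and `misses` (planted miss table with `rescuable` flags).
#' @export
truth_summary <- function(world) {
  stopifnot(inherits(world, "ddr_world"))
  cfg <- world$config
  tr <- world$truth
  grp <- world$catalog$pathway_group[match(tr$anchor_id,
                                           world$catalog$anchor_id)]
  lf <- world$species$lifestyle[match(tr$species_id,
                                      world$species$species_id)]
  non_human <- tr$species_id != cfg$human_species_id
  emp <- tapply(tr$present[non_human],
                list(factor(lf[non_human], LIFESTYLES),
                     factor(grp[non_human], PATHWAY_GROUPS)), mean)
  mult <- cfg$multipliers
  ratio <- outer(mult, mult, `/`)
  list(expected_preservation = cfg$retention,
       empirical_presence = emp,
       expected_length_ratio = ratio,
       expected_footprint = cfg$footprint,
       misses = tr[tr$missed, c("anchor_id", "species_id", "rescuable")])
}
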