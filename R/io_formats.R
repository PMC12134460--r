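#' @title Readers and writers for the pipeline's external formats
#'
#' @description
#' Every external format the pipeline touches has a reader and (where the
#' pipeline also emits it) a writer here: protein FASTA, Orthofinder-style
#' `Orthogroups.tsv`, pairwise ortholog tables, `pfam_scan` output, species
#' metadata, the pathway catalogue, reference-orthology tables and
#' interaction-count tables. Readers validate strictly and raise located
#' errors; no silent coercion. All TSVs are tab-separated UTF-8 with a header
#' row, '.' decimal separator, no quoting, and empty strings for missing
#' values.
#'
#' All domain coordinates in the package are 1-based inclusive (the
#' Pfam/HMMER convention) and are converted nowhere.
#'
#' @name io_formats
NULL

# -- FASTA -------------------------------------------------------------------

#' Read a protein FASTA file
#'
#' One record per predicted protein, taken at face value (isoform collapsing,
#' if any, is the data-preparer's job). Record ids are the first
#' whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @param species_id Species identifier attached to every record.
#' @return A data.frame with columns `protein_id`, `species_id`, `sequence`,
#'   `length` (residues; always equal to `nchar(sequence)`).
#' @export
read_protein_fasta <- function(path, species_id = NA_character_) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) {
    if (all(!nzchar(trimws(lines))))
      return(data.frame(protein_id = character(0),
                        species_id = character(0),
                        sequence = character(0), length = integer(0),
                        stringsAsFactors = FALSE))
    abort("%s: not a FASTA file (no '>' header found)", path)
  }
  # locate sequence-less headers before handing off to Biostrings
  hidx <- which(hdr)
  next_hdr <- c(hidx[-1], length(lines) + 1L)
  for (i in seq_along(hidx)) {
    body <- lines[seq.int(hidx[i] + 1L, length.out = next_hdr[i] - hidx[i] - 1L)]
    if (!any(nzchar(trimws(body))))
      abort("%s: record at line %d has a header but no sequence", path, hidx[i])
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    abort("%s: duplicate protein id(s): %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(protein_id = ids,
             species_id = rep(species_id, length(aa)),
             sequence = as.character(aa),
             length = Biostrings::width(aa),
             stringsAsFactors = FALSE)
}

#' Write a protein FASTA file
#'
#' @param proteins data.frame with `protein_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- proteins$protein_id
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

# -- Orthogroups.tsv ---------------------------------------------------------

#' Read an Orthofinder-style Orthogroups.tsv
#'
#' First column is the orthogroup id; remaining columns are species, cells
#' are comma(+space)-separated accession lists, possibly empty. Every
#' accession may appear in at most one orthogroup.
#'
#' @param path Path to the table.
#' @param species_list Declared species ids; any other species column is an
#'   error.
#' @return Long-format data.frame `orthogroup_id`, `species_id`, `accession`
#'   (one row per member; species with empty cells contribute no rows). The
#'   declared species order is kept in `attr(, "species")`.
#' @export
read_orthogroups <- function(path, species_list) {
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = NULL, colClasses = "character")
  if (ncol(df) < 2L) abort("%s: expected an orthogroup column plus species columns", path)
  sp_cols <- names(df)[-1]
  unknown <- setdiff(sp_cols, species_list)
  if (length(unknown) > 0L)
    abort("%s: unknown species column(s): %s", path,
          paste(unknown, collapse = ", "))
  og <- df[[1]]
  if (anyDuplicated(og))
    abort("%s: duplicated orthogroup id(s): %s", path,
          paste(unique(og[duplicated(og)]), collapse = ", "))
  pieces <- lapply(sp_cols, function(sp) {
    members <- strsplit(df[[sp]], ",[ ]*")
    n <- lengths(members)
    out <- data.frame(orthogroup_id = rep(og, n),
                      species_id = rep(sp, sum(n)),
                      accession = trimws(unlist(members, use.names = FALSE)),
                      stringsAsFactors = FALSE)
    out[nzchar(out$accession), , drop = FALSE]
  })
  long <- do.call(rbind, pieces)
  rownames(long) <- NULL
  dup <- unique(long$accession[duplicated(long[c("species_id", "accession")])])
  # accession-to-orthogroup uniqueness across the whole table
  per_acc <- unique(long[c("orthogroup_id", "accession")])
  multi <- unique(per_acc$accession[duplicated(per_acc$accession)])
  if (length(multi) > 0L)
    abort("%s: accession(s) in more than one orthogroup: %s", path,
          paste(utils::head(multi, 5L), collapse = ", "))
  if (length(dup) > 0L)
    abort("%s: accession(s) listed twice within a species: %s", path,
          paste(utils::head(dup, 5L), collapse = ", "))
  attr(long, "species") <- sp_cols
  long
}

#' Write an Orthofinder-style Orthogroups.tsv
#'
#' @param orthogroups Long-format data.frame as returned by
#'   [read_orthogroups()].
#' @param path Output path.
#' @param species_list Species column order; defaults to the attribute stored
#'   on `orthogroups`.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(orthogroups, path,
                              species_list = attr(orthogroups, "species")) {
  if (is.null(species_list))
    species_list <- sort(unique(orthogroups$species_id))
  ogs <- unique(orthogroups$orthogroup_id)
  wide <- data.frame(Orthogroup = ogs, stringsAsFactors = FALSE,
                     check.names = FALSE)
  key <- paste(orthogroups$orthogroup_id, orthogroups$species_id, sep = "\r")
  joined <- vapply(split(orthogroups$accession, factor(key)),
                   paste, character(1), collapse = ", ")
  for (sp in species_list) {
    cells <- joined[paste(ogs, sp, sep = "\r")]
    cells[is.na(cells)] <- ""
    wide[[sp]] <- unname(cells)
  }
  write_tsv_strict(wide, path)
}

# -- Pairwise ortholog tables ------------------------------------------------

#' Read a pairwise ortholog table
#'
#' Orthofinder-style three-column table: `Orthogroup`, then one column per
#' species (named by species id), each cell a comma(+space)-separated
#' accession list. Both gene lists must be non-empty on every row.
#'
#' @param path Path to the table.
#' @return data.frame `orthogroup_id`, `species_a`, `species_b`, `gene_a`,
#'   `gene_b`, expanded to one row per (gene_a, gene_b) pair.
#' @export
read_pairwise_orthologs <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = NULL, colClasses = "character")
  if (ncol(df) != 3L)
    abort("%s: expected 3 columns (Orthogroup, species A, species B), got %d",
          path, ncol(df))
  sp_a <- names(df)[2]; sp_b <- names(df)[3]
  ga <- strsplit(df[[2]], ",[ ]*")
  gb <- strsplit(df[[3]], ",[ ]*")
  empty <- which(vapply(ga, function(x) !any(nzchar(x)), logical(1)) |
                 vapply(gb, function(x) !any(nzchar(x)), logical(1)))
  if (length(empty) > 0L)
    abort("%s: empty gene list on data row %d", path, empty[1])
  rows <- mapply(function(og, a, b) {
    grid <- expand.grid(gene_a = a, gene_b = b, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    grid$orthogroup_id <- og
    grid
  }, df[[1]], ga, gb, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$species_a <- sp_a
  out$species_b <- sp_b
  out[c("orthogroup_id", "species_a", "species_b", "gene_a", "gene_b")]
}

#' Write a pairwise ortholog table
#'
#' @param pairs Expanded pair data.frame as returned by
#'   [read_pairwise_orthologs()] (single species pair).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairwise_orthologs <- function(pairs, path) {
  sp_a <- unique(pairs$species_a); sp_b <- unique(pairs$species_b)
  stopifnot(length(sp_a) == 1L, length(sp_b) == 1L)
  ogs <- unique(pairs$orthogroup_id)
  f <- factor(pairs$orthogroup_id, levels = ogs)
  ca <- vapply(split(pairs$gene_a, f),
               function(x) paste(unique(x), collapse = ", "), character(1))
  cb <- vapply(split(pairs$gene_b, f),
               function(x) paste(unique(x), collapse = ", "), character(1))
  wide <- data.frame(Orthogroup = ogs, a = unname(ca), b = unname(cb),
                     stringsAsFactors = FALSE)
  names(wide)[2:3] <- c(sp_a, sp_b)
  write_tsv_strict(wide, path)
}

# -- pfam_scan output --------------------------------------------------------

PFAM_COLS <- c("protein_id", "alignment_start", "alignment_end",
               "envelope_start", "envelope_end", "pfam_accession",
               "domain_name", "hmm_type", "hmm_start", "hmm_end",
               "hmm_length", "bit_score", "e_value", "significance", "clan")

#' Read pfam_scan output
#'
#' Parses the whitespace-delimited `pfam_scan.pl` table ('#'-prefixed and
#' blank lines are comments). Coordinates are 1-based inclusive; the envelope
#' must contain the alignment interval.
#'
#' @param path Path to a pfam_scan output file.
#' @return data.frame with columns `protein_id`, `alignment_start`,
#'   `alignment_end`, `envelope_start`, `envelope_end`, `pfam_accession`,
#'   `domain_name`, `bit_score`, `e_value`.
#' @export
read_pfam_hits <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  empty <- data.frame(protein_id = character(0),
                      alignment_start = integer(0), alignment_end = integer(0),
                      envelope_start = integer(0), envelope_end = integer(0),
                      pfam_accession = character(0), domain_name = character(0),
                      bit_score = numeric(0), e_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(keep) == 0L) return(empty)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 13L))
    abort("%s: line %d: expected at least 13 whitespace-delimited fields, got %d",
          path, keep[which(nf < 13L)[1]], min(nf))
  m <- do.call(rbind, fields)
  to_int <- function(col, what) {
    v <- suppressWarnings(as.integer(m[, col]))
    bad <- which(is.na(v) | suppressWarnings(as.numeric(m[, col])) != v)
    if (length(bad) > 0L)
      abort("%s: line %d: non-integer %s '%s'", path, keep[bad[1]], what,
            m[bad[1], col])
    v
  }
  out <- data.frame(
    protein_id = m[, 1],
    alignment_start = to_int(2, "alignment start"),
    alignment_end = to_int(3, "alignment end"),
    envelope_start = to_int(4, "envelope start"),
    envelope_end = to_int(5, "envelope end"),
    pfam_accession = m[, 6],
    domain_name = m[, 7],
    bit_score = as.numeric(m[, 12]),
    e_value = as.numeric(m[, 13]),
    stringsAsFactors = FALSE)
  bad <- which(out$envelope_start < 1L |
               out$envelope_start > out$envelope_end)
  if (length(bad) > 0L)
    abort("%s: line %d: invalid envelope [%d, %d]", path, keep[bad[1]],
          out$envelope_start[bad[1]], out$envelope_end[bad[1]])
  bad <- which(out$alignment_start < out$envelope_start |
               out$alignment_end > out$envelope_end |
               out$alignment_start > out$alignment_end)
  if (length(bad) > 0L)
    abort("%s: line %d: envelope [%d, %d] does not contain alignment [%d, %d]",
          path, keep[bad[1]], out$envelope_start[bad[1]],
          out$envelope_end[bad[1]], out$alignment_start[bad[1]],
          out$alignment_end[bad[1]])
  out
}

#' Write pfam_scan-style output
#'
#' @param hits data.frame as returned by [read_pfam_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfam_hits <- function(hits, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# pfam_scan-style domain hits",
               paste("# <seq id> <alignment start> <alignment end>",
                     "<envelope start> <envelope end> <hmm acc> <hmm name>",
                     "<type> <hmm start> <hmm end> <hmm length> <bit score>",
                     "<E-value> <significance> <clan>")), con)
  if (nrow(hits) > 0L) {
    aln_w <- hits$alignment_end - hits$alignment_start + 1L
    writeLines(sprintf("%s %6d %6d %6d %6d %s %s Domain %d %d %d %8.1f %9.2e 1 No_clan",
                       hits$protein_id, hits$alignment_start,
                       hits$alignment_end, hits$envelope_start,
                       hits$envelope_end, hits$pfam_accession,
                       hits$domain_name, 1L, aln_w, aln_w,
                       hits$bit_score, hits$e_value), con)
  }
  invisible(path)
}

# -- Species metadata --------------------------------------------------------

#' Read the species metadata table
#'
#' @param path TSV with columns `species_id`, `display_name`, `lifestyle`,
#'   `organelle_status`, `clade`, `clade_reference`, `excluded_absences`.
#' @return Validated data.frame; `excluded_absences` is logical. Lifestyles
#'   are one of free_living / extracellular / cytoplasmic / intranuclear;
#'   organelle status is atp_mito_or_plastid / no_atp_mito; every
#'   `clade_reference` must resolve to a declared species.
#' @export
read_species_metadata <- function(path) {
  df <- read_tsv_strict(path, required = c("species_id", "display_name",
                                           "lifestyle", "organelle_status",
                                           "clade", "clade_reference",
                                           "excluded_absences"))
  validate_species_metadata(df)
}

#' @rdname read_species_metadata
#' @param species data.frame in the species metadata layout.
#' @export
validate_species_metadata <- function(species) {
  if (anyDuplicated(species$species_id))
    abort("duplicated species_id in metadata")
  check_vocab(species$lifestyle, LIFESTYLES, "lifestyle")
  check_vocab(species$organelle_status, ORGANELLE_STATUSES, "organelle_status")
  if (is.character(species$excluded_absences))
    species$excluded_absences <- species$excluded_absences %in%
      c("TRUE", "true", "1", "yes")
  species$excluded_absences <- as.logical(species$excluded_absences)
  unresolved <- setdiff(unique(species$clade_reference), species$species_id)
  if (length(unresolved) > 0L)
    abort("clade_reference does not resolve to a declared species: %s",
          paste(unresolved, collapse = ", "))
  by_clade <- tapply(species$clade_reference, species$clade,
                     function(x) length(unique(x)))
  if (any(by_clade != 1L))
    abort("clade(s) with more than one declared reference: %s",
          paste(names(by_clade)[by_clade != 1L], collapse = ", "))
  species
}

#' @rdname read_species_metadata
#' @export
write_species_metadata <- function(species, path) write_tsv_strict(species, path)

# -- Pathway catalogue -------------------------------------------------------

#' Read the pathway catalogue
#'
#' Maps each human anchor protein to exactly one pathway, and each pathway to
#' exactly one of the four pathway groups (DDR, replication, metabolic,
#' housekeeping).
#'
#' @param path TSV with columns `anchor_id`, `pathway`, `pathway_group`.
#' @return Validated data.frame.
#' @export
read_pathway_catalog <- function(path) {
  df <- read_tsv_strict(path, required = c("anchor_id", "pathway",
                                           "pathway_group"))
  validate_pathway_catalog(df)
}

#' @rdname read_pathway_catalog
#' @param catalog data.frame in the pathway catalogue layout.
#' @export
validate_pathway_catalog <- function(catalog) {
  if (anyDuplicated(catalog$anchor_id))
    abort("anchor(s) assigned to more than one pathway: %s",
          paste(unique(catalog$anchor_id[duplicated(catalog$anchor_id)]),
                collapse = ", "))
  check_vocab(catalog$pathway_group, PATHWAY_GROUPS, "pathway_group")
  per_pw <- tapply(catalog$pathway_group, catalog$pathway,
                   function(x) length(unique(x)))
  if (any(per_pw != 1L))
    abort("pathway(s) assigned to more than one group: %s",
          paste(names(per_pw)[per_pw != 1L], collapse = ", "))
  catalog
}

#' @rdname read_pathway_catalog
#' @export
write_pathway_catalog <- function(catalog, path) write_tsv_strict(catalog, path)

# -- Reference orthology (InParanoiDB-style lookup, ingested as a table) -----

#' Read a reference-orthology table
#'
#' One row per (clade reference species, human anchor) with the reference
#' accession independently confirmed orthologous to the anchor. Stands in for
#' a pairwise orthology database lookup; only anchors with a confirmed
#' reference orthologue appear.
#'
#' @param path TSV with columns `reference_species`, `anchor_id`,
#'   `reference_accession`.
#' @return data.frame.
#' @export
read_reference_orthology <- function(path) {
  df <- read_tsv_strict(path, required = c("reference_species", "anchor_id",
                                           "reference_accession"))
  if (anyDuplicated(df[c("reference_species", "anchor_id")]))
    abort("duplicate (reference_species, anchor_id) row(s) in %s", path)
  df
}

#' @rdname read_reference_orthology
#' @param ref_orthology data.frame in the reference-orthology layout.
#' @export
write_reference_orthology <- function(ref_orthology, path)
  write_tsv_strict(ref_orthology, path)

# -- Interaction counts ------------------------------------------------------

#' Read a protein interaction-count table
#'
#' @param path TSV with columns `protein_id`, `physical_interaction_count`
#'   (non-negative integers).
#' @return data.frame.
#' @export
read_interaction_counts <- function(path) {
  df <- read_tsv_strict(path, required = c("protein_id",
                                           "physical_interaction_count"))
  cnt <- df$physical_interaction_count
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != as.integer(cnt)))
    abort("%s: physical_interaction_count must be non-negative integers", path)
  df$physical_interaction_count <- as.integer(cnt)
  df
}

#' @rdname read_interaction_counts
#' @param counts data.frame in the interaction-count layout.
#' @export
write_interaction_counts <- function(counts, path) write_tsv_strict(counts, path)
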