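#' @title Domain / interdomain length decomposition
#'
#' @description
#' Decomposes each protein into functional-domain length `D` (residues
#' covered by the union of its Pfam hit envelopes) and interdomain length
#' `I = protein_length - D`, which includes N- and C-terminal tails. The
#' footprint is `D / protein_length`; domain density is the number of
#' individual domain hits per domain-covered residue. `D + I` equals the
#' protein length exactly for every protein.
#'
#' @name domains
NULL

# grouped running cummax for rows sorted by group; gi = dense integer group
# index, x bounded positive integers
grouped_cummax <- function(x, gi) {
  k <- max(x) + 1
  cummax(x + as.numeric(gi) * k) - as.numeric(gi) * k
}

# Vectorised merge over many proteins at once. pid/start/end are parallel
# vectors; returns merged segments sorted by (pid, start).
merge_engine <- function(pid, start, end) {
  if (length(pid) == 0L)
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  o <- order(pid, start, end)
  pid <- pid[o]; start <- start[o]; end <- end[o]
  gi <- cumsum(!duplicated(pid))
  run_max <- grouped_cummax(end, gi)
  prev_max <- c(-Inf, run_max[-length(run_max)])
  first <- !duplicated(pid)
  # a new segment starts when at least one residue is uncovered before it;
  # bookended intervals (prev end + 1 == start) coalesce
  new_seg <- first | start > prev_max + 1
  seg <- cumsum(new_seg)
  seg_end <- grouped_cummax(end, seg)
  last_of_seg <- !duplicated(seg, fromLast = TRUE)
  data.frame(protein_id = pid[new_seg],
             start = start[new_seg],
             end = as.integer(seg_end[last_of_seg]),
             stringsAsFactors = FALSE)
}

#' Merge 1-based inclusive intervals
#'
#' Returns the disjoint sorted union of the input intervals. Overlapping or
#' bookended intervals (`end + 1 == next start`) are coalesced, so no residue
#' is counted twice when summing covered length.
#'
#' @param intervals data.frame (or 2-column matrix) with columns `start`,
#'   `end`, 1-based inclusive, `start <= end`.
#' @return data.frame with columns `start`, `end`, pairwise disjoint, sorted.
#' @export
#' @examples
#' merge_intervals(data.frame(start = c(1, 5), end = c(10, 20)))
merge_intervals <- function(intervals) {
  if (is.matrix(intervals))
    intervals <- data.frame(start = intervals[, 1], end = intervals[, 2])
  stopifnot(all(c("start", "end") %in% names(intervals)))
  s <- as.integer(intervals$start); e <- as.integer(intervals$end)
  if (length(s) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  if (any(is.na(s)) || any(is.na(e))) abort("intervals contain NA coordinates")
  if (any(s < 1L)) abort("interval start below 1 (coordinates are 1-based)")
  bad <- which(s > e)
  if (length(bad) > 0L)
    abort("interval with start > end: [%d, %d]", s[bad[1]], e[bad[1]])
  m <- merge_engine(rep("x", length(s)), s, e)
  data.frame(start = m$start, end = m$end)
}

#' Compute the domain architecture of one protein
#'
#' @param protein A one-row data.frame (or list) with `protein_id` and
#'   `length` (residues).
#' @param hits Pfam hit rows for this protein ([read_pfam_hits()] layout);
#'   may be empty. Envelope coordinates define domain extent. A hit outside
#'   `[1, length]` is an error (it signals an annotation/length mismatch),
#'   never clipped.
#' @return One-row data.frame: `protein_id`, `protein_length`, `n_domains`
#'   (raw hits, before merging), `n_segments` (merged segments),
#'   `domain_length`, `interdomain_length`, `footprint`.
#' @export
domain_architecture <- function(protein, hits) {
  arch <- architecture_table(
    data.frame(protein_id = protein$protein_id, length = protein$length,
               stringsAsFactors = FALSE),
    hits)
  arch
}

#' Compute domain architectures for many proteins
#'
#' @param proteins data.frame with `protein_id` and `length` (residues);
#'   one row per protein.
#' @param hits Pfam hit rows ([read_pfam_hits()] layout) for any subset of
#'   those proteins. Hits for unknown proteins, or outside `[1, length]`,
#'   are errors.
#' @return data.frame, one row per protein in `proteins`, with the columns
#'   of [domain_architecture()]. Proteins without hits get
#'   `domain_length = 0`, `footprint = 0`,
#'   `interdomain_length = protein_length`.
#' @export
architecture_table <- function(proteins, hits) {
  stopifnot(all(c("protein_id", "length") %in% names(proteins)))
  if (anyDuplicated(proteins$protein_id))
    abort("duplicated protein_id in proteins table")
  n_hits <- integer(nrow(proteins))
  names(n_hits) <- proteins$protein_id
  dlen <- n_hits
  nseg <- n_hits
  if (!is.null(hits) && nrow(hits) > 0L) {
    idx <- match(hits$protein_id, proteins$protein_id)
    if (anyNA(idx))
      abort("hit for unknown protein: %s",
            hits$protein_id[which(is.na(idx))[1]])
    plen <- proteins$length[idx]
    bad <- which(hits$envelope_start < 1L | hits$envelope_end > plen)
    if (length(bad) > 0L)
      abort("hit [%d, %d] exceeds protein %s (length %d)",
            hits$envelope_start[bad[1]], hits$envelope_end[bad[1]],
            hits$protein_id[bad[1]], plen[bad[1]])
    bad <- which(hits$envelope_start > hits$envelope_end)
    if (length(bad) > 0L)
      abort("hit with start > end on protein %s", hits$protein_id[bad[1]])
    tb <- table(factor(hits$protein_id, levels = proteins$protein_id))
    n_hits[] <- as.integer(tb)
    merged <- merge_engine(hits$protein_id, hits$envelope_start,
                           hits$envelope_end)
    widths <- merged$end - merged$start + 1L
    d <- rowsum(widths, merged$protein_id)
    dlen[rownames(d)] <- as.integer(d)
    s <- rowsum(rep(1L, nrow(merged)), merged$protein_id)
    nseg[rownames(s)] <- as.integer(s)
  }
  out <- data.frame(protein_id = proteins$protein_id,
                    protein_length = as.integer(proteins$length),
                    n_domains = unname(n_hits),
                    n_segments = unname(nseg),
                    domain_length = unname(dlen),
                    stringsAsFactors = FALSE)
  out$interdomain_length <- out$protein_length - out$domain_length
  out$footprint <- out$domain_length / out$protein_length
  out
}

#' Per-(species, pathway-group) length decomposition summary
#'
#' Aggregates present representative proteins into per-cell means of protein
#' length, domain length `D`, interdomain length `I` and footprint, plus the
#' cell's domain density (total raw hits per domain-covered residue, also per
#' 100 covered residues). Cells with zero present proteins are omitted.
#'
#' @param architectures Output of [architecture_table()] covering every
#'   present representative protein.
#' @param matrix Presence/length matrix ([build_presence_matrix()]).
#' @param catalog Pathway catalogue.
#' @param species Species metadata.
#' @return data.frame with one row per non-empty (species_id, pathway_group)
#'   cell.
#' @export
group_length_decomposition <- function(architectures, matrix, catalog,
                                       species) {
  pres <- matrix[matrix$status == "present", , drop = FALSE]
  idx <- match(pres$representative_accession, architectures$protein_id)
  if (anyNA(idx))
    abort("no architecture for representative protein %s",
          pres$representative_accession[which(is.na(idx))[1]])
  grp <- catalog$pathway_group[match(pres$anchor_id, catalog$anchor_id)]
  cell <- interaction(pres$species_id, grp, drop = TRUE, sep = "\r")
  a <- architectures[idx, , drop = FALSE]
  agg <- data.frame(
    key = levels(cell),
    n = as.integer(table(cell)),
    mean_length = as.numeric(tapply(a$protein_length, cell, mean)),
    mean_domain_length = as.numeric(tapply(a$domain_length, cell, mean)),
    mean_interdomain_length = as.numeric(tapply(a$interdomain_length, cell,
                                                mean)),
    mean_footprint = as.numeric(tapply(a$footprint, cell, mean)),
    sum_domains = as.numeric(tapply(a$n_domains, cell, sum)),
    sum_domain_length = as.numeric(tapply(a$domain_length, cell, sum)),
    stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  agg$species_id <- vapply(parts, `[`, character(1), 1L)
  agg$pathway_group <- vapply(parts, `[`, character(1), 2L)
  agg$domain_density <- ifelse(agg$sum_domain_length > 0,
                               agg$sum_domains / agg$sum_domain_length, NA_real_)
  agg$domain_density_per_100 <- 100 * agg$domain_density
  rownames(agg) <- NULL
  agg[c("species_id", "pathway_group", "n", "mean_length",
        "mean_domain_length", "mean_interdomain_length", "mean_footprint",
        "domain_density", "domain_density_per_100")]
}

#' Per-species length profile for correlations
#'
#' One row per species: mean protein length, mean domain length and mean
#' interdomain length over all present representative proteins.
#'
#' @inheritParams group_length_decomposition
#' @return data.frame `species_id`, `n`, `mean_length`, `mean_domain_length`,
#'   `mean_interdomain_length`.
#' @export
species_length_profile <- function(architectures, matrix) {
  pres <- matrix[matrix$status == "present", , drop = FALSE]
  idx <- match(pres$representative_accession, architectures$protein_id)
  if (anyNA(idx))
    abort("no architecture for representative protein %s",
          pres$representative_accession[which(is.na(idx))[1]])
  a <- architectures[idx, , drop = FALSE]
  sp <- factor(pres$species_id)
  data.frame(species_id = levels(sp),
             n = as.integer(table(sp)),
             mean_length = as.numeric(tapply(a$protein_length, sp, mean)),
             mean_domain_length = as.numeric(tapply(a$domain_length, sp, mean)),
             mean_interdomain_length =
               as.numeric(tapply(a$interdomain_length, sp, mean)),
             stringsAsFactors = FALSE)
}

#' Spearman correlations among length components
#'
#' Correlates protein length, interdomain length and functional-domain
#' length across observation units (species-level means by default; protein
#' level behind the `profile` argument — pass per-protein rows instead).
#'
#' @param profile data.frame with columns `mean_length`,
#'   `mean_domain_length`, `mean_interdomain_length` (one row per unit).
#' @return data.frame with one row per pair (`length~interdomain`,
#'   `length~domain`, `interdomain~domain`): `rho`, `n`, `df`, `p`.
#'   Constant inputs yield `NA` coefficients.
#' @export
length_correlations <- function(profile) {
  need <- c("mean_length", "mean_domain_length", "mean_interdomain_length")
  stopifnot(all(need %in% names(profile)))
  if (nrow(profile) < 3L) abort("need at least 3 observation units")
  pairs <- list(
    c("length~interdomain", "mean_length", "mean_interdomain_length"),
    c("length~domain", "mean_length", "mean_domain_length"),
    c("interdomain~domain", "mean_interdomain_length", "mean_domain_length"))
  rows <- lapply(pairs, function(p) {
    ct <- spearman_test(profile[[p[2]]], profile[[p[3]]])
    data.frame(pair = p[1], rho = ct$rho, n = ct$n, df = ct$df, p = ct$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
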