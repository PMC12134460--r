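#' @title Pathway preservation scoring
#'
#' @description
#' The preservation value of a pathway in a species is the fraction of the
#' pathway's anchor proteins with an identified orthologue in that species,
#' over the assessable (non-excluded) anchors. Aggregation helpers compute
#' unweighted means by species, pathway or lifestyle x pathway-group cell,
#' and export the wide presence/length heatmap matrix.
#'
#' @name preservation
NULL

#' Per-(species, pathway) preservation values
#'
#' @param matrix Presence matrix ([build_presence_matrix()]).
#' @param catalog Pathway catalogue; every anchor in the matrix must appear
#'   in it.
#' @return data.frame `species_id`, `pathway`, `pathway_group`,
#'   `n_assessable`, `n_present`, `preservation`. Excluded cells are removed
#'   from numerator and denominator; a pathway with zero assessable anchors
#'   in a species yields `NA`.
#' @export
pathway_preservation <- function(matrix, catalog) {
  idx <- match(matrix$anchor_id, catalog$anchor_id)
  if (anyNA(idx))
    abort("anchor %s in matrix is absent from the catalogue",
          matrix$anchor_id[which(is.na(idx))[1]])
  pw <- catalog$pathway[idx]
  cell <- interaction(matrix$species_id, pw, drop = FALSE, sep = "\r")
  assessable <- matrix$status != "excluded"
  n_assess <- tapply(assessable, cell, sum)
  n_assess[is.na(n_assess)] <- 0L
  n_pres <- tapply(matrix$status == "present", cell, sum)
  n_pres[is.na(n_pres)] <- 0L
  key <- names(n_assess)
  parts <- strsplit(key, "\r", fixed = TRUE)
  out <- data.frame(species_id = vapply(parts, `[`, character(1), 1L),
                    pathway = vapply(parts, `[`, character(1), 2L),
                    n_assessable = as.integer(n_assess),
                    n_present = as.integer(n_pres),
                    stringsAsFactors = FALSE)
  out$pathway_group <- catalog$pathway_group[match(out$pathway,
                                                   catalog$pathway)]
  out$preservation <- ifelse(out$n_assessable > 0L,
                             out$n_present / out$n_assessable, NA_real_)
  rownames(out) <- NULL
  out[c("species_id", "pathway", "pathway_group", "n_assessable",
        "n_present", "preservation")]
}

#' Mean preservation summaries
#'
#' Unweighted means of per-(species, pathway) preservation values within
#' each cell of the requested grouping; `NA` values (pathways with no
#' assessable anchors) are omitted and empty cells are reported as `NA`,
#' never zero. The per-species summary is the mean over that species'
#' pathway values (not the pooled protein fraction), so small pathways are
#' not swamped; pass `pooled = TRUE` for the pooled fraction instead.
#'
#' @param table Output of [pathway_preservation()].
#' @param by `"species"`, `"pathway"`, or `"lifestyle_group"` (lifestyle x
#'   pathway-group cells; requires `species`).
#' @param species Species metadata (needed for `by = "lifestyle_group"`,
#'   and attached to the species summary when given).
#' @param pooled For `by = "species"`: pool anchors instead of averaging
#'   pathway values.
#' @return data.frame with the grouping columns, `n` (values averaged) and
#'   `mean_preservation`.
#' @export
mean_preservation <- function(table, by = c("species", "pathway",
                                            "lifestyle_group"),
                              species = NULL, pooled = FALSE) {
  by <- match.arg(by)
  tab <- table[!is.na(table$preservation), , drop = FALSE]
  if (by == "species") {
    f <- factor(tab$species_id)
    out <- data.frame(species_id = levels(f), n = as.integer(table(f)),
                      mean_preservation = if (pooled)
                        as.numeric(tapply(tab$n_present, f, sum) /
                                   tapply(tab$n_assessable, f, sum)) else
                        as.numeric(tapply(tab$preservation, f, mean)),
                      stringsAsFactors = FALSE)
    if (!is.null(species))
      out$lifestyle <- species$lifestyle[match(out$species_id,
                                               species$species_id)]
  } else if (by == "pathway") {
    f <- factor(tab$pathway)
    out <- data.frame(pathway = levels(f), n = as.integer(table(f)),
                      mean_preservation =
                        as.numeric(tapply(tab$preservation, f, mean)),
                      stringsAsFactors = FALSE)
    out$pathway_group <- tab$pathway_group[match(out$pathway, tab$pathway)]
  } else {
    if (is.null(species))
      abort("species metadata is required for by = 'lifestyle_group'")
    lf <- species$lifestyle[match(tab$species_id, species$species_id)]
    cell <- interaction(factor(lf, LIFESTYLES),
                        factor(tab$pathway_group, PATHWAY_GROUPS),
                        drop = FALSE, sep = "\r")
    mean_v <- tapply(tab$preservation, cell, mean)
    n_v <- tapply(tab$preservation, cell, length)
    parts <- strsplit(names(mean_v), "\r", fixed = TRUE)
    out <- data.frame(lifestyle = vapply(parts, `[`, character(1), 1L),
                      pathway_group = vapply(parts, `[`, character(1), 2L),
                      n = ifelse(is.na(n_v), 0L, as.integer(n_v)),
                      mean_preservation = as.numeric(mean_v),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Per-species DDR repertoire size
#'
#' @param matrix Presence matrix.
#' @param catalog Pathway catalogue defining the DDR anchor set.
#' @return data.frame `species_id`, `n_ddr_present` (count of DDR anchors
#'   present, in `[0, number of DDR anchors]`).
#' @export
ddr_repertoire_size <- function(matrix, catalog) {
  ddr <- catalog$anchor_id[catalog$pathway_group == "DDR"]
  m <- matrix[matrix$anchor_id %in% ddr, , drop = FALSE]
  f <- factor(m$species_id)
  data.frame(species_id = levels(f),
             n_ddr_present = as.integer(tapply(m$status == "present", f,
                                               sum)),
             stringsAsFactors = FALSE)
}

#' Wide presence/length heatmap matrix
#'
#' Species x anchors table of representative lengths; anchors (columns) are
#' grouped by pathway in catalogue order. Absent cells are blank, excluded
#' cells are rendered `NA` (distinct from absent).
#'
#' @param matrix Presence matrix.
#' @param catalog Pathway catalogue (column order).
#' @param pathway_order Optional pathway ordering; defaults to catalogue
#'   order.
#' @return data.frame with `species_id` plus one character column per
#'   anchor.
#' @export
heatmap_matrix <- function(matrix, catalog, pathway_order = NULL) {
  if (is.null(pathway_order)) pathway_order <- unique(catalog$pathway)
  cat_ord <- catalog[order(match(catalog$pathway, pathway_order)), ,
                     drop = FALSE]
  anchors <- cat_ord$anchor_id
  sps <- unique(matrix$species_id)
  cellval <- ifelse(matrix$status == "present",
                    as.character(matrix$representative_length),
                    ifelse(matrix$status == "excluded", "NA", ""))
  m <- base::matrix("", nrow = length(sps), ncol = length(anchors),
                    dimnames = list(sps, anchors))
  m[cbind(match(matrix$species_id, sps),
          match(matrix$anchor_id, anchors))] <- cellval
  out <- data.frame(species_id = sps, m, stringsAsFactors = FALSE,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a heatmap matrix back into statuses
#'
#' Inverse of [heatmap_matrix()] up to representative length and status:
#' blank cells become `absent`, `NA` cells `excluded`, numbers `present`.
#'
#' @param path Path to a heatmap TSV written with [write_tsv_strict()]
#'   semantics (empty string for blanks).
#' @return Long data.frame `anchor_id`, `species_id`, `status`,
#'   `representative_length`.
#' @export
read_heatmap_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = NULL, colClasses = "character")
  anchors <- names(df)[-1]
  long <- data.frame(
    anchor_id = rep(anchors, each = nrow(df)),
    species_id = rep(df$species_id, times = length(anchors)),
    cell = unlist(df[anchors], use.names = FALSE),
    stringsAsFactors = FALSE)
  long$status <- ifelse(long$cell == "", "absent",
                        ifelse(long$cell == "NA", "excluded", "present"))
  long$representative_length <- ifelse(long$status == "present",
                                       suppressWarnings(as.numeric(long$cell)),
                                       NA_real_)
  long$cell <- NULL
  long
}
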