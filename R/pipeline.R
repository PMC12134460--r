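#' @title End-to-end pipeline orchestration
#'
#' @description
#' Runs the full comparative analysis from a single configuration — either a
#' directory of input files in the external formats, or a synthetic world
#' generated on the fly — and writes every result table as deterministic
#' TSVs: the presence/length matrix, preservation tables and summaries, the
#' heatmap matrix, domain architectures and decomposition summaries,
#' correlations, ANOVAs, length ratios, the conserved-group audit and the
#' interaction-count summary, plus a run manifest. Outputs are pure
#' functions of inputs + configuration + seed; a fixed seed gives
#' byte-identical files across runs.
#'
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param input_dir Directory of input files ([read_world()] layout), or
#'   `NULL` to generate a synthetic world.
#' @param world A [world_config()] used when `input_dir` is `NULL`; its seed
#'   is replaced by `seed`.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param seed Integer seed fixing every stochastic step.
#' @param human_species_id Anchor species id.
#' @param rescue Apply the clade-reference bait rescue (default `TRUE`).
#' @param threshold Conservation threshold for the audit.
#' @param failure_prob Assumed calling-failure probability for the audit.
#' @param rep_rule Representative length rule, `"max"` or `"mean"`.
#' @param ss_type Sum-of-squares type for the two-way ANOVAs (1, 2 or 3).
#' @param corr_unit Observation unit for the length correlations:
#'   `"species"` (per-species means; the default) or `"protein"` (pooled
#'   proteins).
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir = NULL, world = world_config(),
                       out_dir = NULL, seed = 1L,
                       human_species_id = world$human_species_id %||% "hsap",
                       rescue = TRUE, threshold = 0.95,
                       failure_prob = 0.045,
                       rep_rule = c("max", "mean"), ss_type = 3,
                       corr_unit = c("species", "protein")) {
  cfg <- list(input_dir = input_dir, world = world, out_dir = out_dir,
              seed = as.integer(seed), human_species_id = human_species_id,
              rescue = isTRUE(rescue), threshold = threshold,
              failure_prob = failure_prob, rep_rule = match.arg(rep_rule),
              ss_type = ss_type, corr_unit = match.arg(corr_unit))
  class(cfg) <- "run_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    abort("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full pipeline
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage count logging.
#' @return Invisibly, a list with every intermediate and final table
#'   (`inputs`, `family_map`, `matrix`, `audit`, `preservation`, summaries,
#'   `repertoire`, `heatmap`, `architectures`, `decomposition`, `profile`,
#'   `correlations`, `anova`, `ratios`, `interaction_summary`, `manifest`).
#'   When `config$out_dir` is set, each table is also written there as a
#'   TSV.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  inputs <- stage("inputs", {
    if (!is.null(config$input_dir)) {
      read_world(config$input_dir)
    } else {
      wc <- config$world
      wc$seed <- config$seed
      generate_world(wc)
    }
  })
  say("inputs: %d species, %d anchors, %d proteins",
      nrow(inputs$species), nrow(inputs$catalog), nrow(inputs$proteins))

  fam <- stage("family_map",
               build_family_map(inputs$orthogroups, inputs$catalog,
                                config$human_species_id))
  say("family map: %d/%d anchors assigned", sum(!is.na(fam$orthogroup_id)),
      nrow(fam))

  mat <- stage("presence_matrix",
               build_presence_matrix(fam, inputs$orthogroups,
                                     inputs$proteins, inputs$species,
                                     rep_rule = config$rep_rule))
  if (config$rescue) {
    before <- sum(mat$status == "present")
    mat <- stage("rescue",
                 rescue_missing(mat, inputs$pairs, inputs$species,
                                inputs$reference_orthology, inputs$proteins,
                                rep_rule = config$rep_rule))
    say("rescue: %d entr(ies) recovered",
        sum(mat$status == "present") - before)
  }

  audit <- stage("audit",
                 audit_conserved_groups(mat, threshold = config$threshold,
                                        failure_prob = config$failure_prob,
                                        drop_species =
                                          config$human_species_id))
  say("audit: %d conserved group(s), p_fail range [%s, %s]", nrow(audit),
      format(suppressWarnings(min(audit$p_fail))),
      format(suppressWarnings(max(audit$p_fail))))

  pres <- stage("preservation", pathway_preservation(mat, inputs$catalog))
  pres_sp <- mean_preservation(pres, by = "species",
                               species = inputs$species)
  pres_pw <- mean_preservation(pres, by = "pathway")
  pres_lg <- mean_preservation(pres, by = "lifestyle_group",
                               species = inputs$species)
  rep_size <- ddr_repertoire_size(mat, inputs$catalog)
  heat <- heatmap_matrix(mat, inputs$catalog)

  arch <- stage("architectures",
                architecture_table(
                  data.frame(protein_id = inputs$proteins$accession,
                             length = inputs$proteins$length,
                             stringsAsFactors = FALSE),
                  inputs$pfam_hits))
  say("architectures: %d proteins scored, %d with domains", nrow(arch),
      sum(arch$n_domains > 0))

  decomp <- stage("decomposition",
                  group_length_decomposition(arch, mat, inputs$catalog,
                                             inputs$species))
  profile <- species_length_profile(arch, mat)
  corr <- stage("correlations", {
    if (config$corr_unit == "species") length_correlations(profile)
    else {
      presm <- mat[mat$status == "present", , drop = FALSE]
      a <- arch[match(presm$representative_accession, arch$protein_id), ]
      length_correlations(data.frame(
        mean_length = a$protein_length,
        mean_domain_length = a$domain_length,
        mean_interdomain_length = a$interdomain_length))
    }
  })

  anovas <- stage("anova", {
    lf <- inputs$species$lifestyle[match(pres_sp$species_id,
                                         inputs$species$species_id)]
    a1 <- one_way_anova(pres_sp$mean_preservation, lf)
    a1$analysis <- "preservation~lifestyle"
    d_lf <- inputs$species$lifestyle[match(decomp$species_id,
                                           inputs$species$species_id)]
    d_st <- inputs$species$organelle_status[match(decomp$species_id,
                                                  inputs$species$species_id)]
    a2 <- two_way_anova(decomp$mean_length, d_lf, decomp$pathway_group,
                        ss_type = config$ss_type)
    a2$analysis <- "length~lifestyle*group"
    a3 <- two_way_anova(decomp$mean_length, d_st, decomp$pathway_group,
                        ss_type = config$ss_type)
    a3$analysis <- "length~status*group"
    a4 <- one_way_anova(decomp$mean_domain_length, decomp$pathway_group)
    a4$analysis <- "domain_length~group"
    a5 <- one_way_anova(decomp$mean_interdomain_length,
                        decomp$pathway_group)
    a5$analysis <- "interdomain_length~group"
    out <- rbind(a1, a2, a3, a4, a5)
    out[c("analysis", setdiff(names(out), "analysis"))]
  })

  ratios <- stage("ratios", {
    presm <- mat[mat$status == "present", , drop = FALSE]
    grp <- inputs$catalog$pathway_group[match(presm$anchor_id,
                                              inputs$catalog$anchor_id)]
    means <- tapply(presm$representative_length, factor(grp), mean)
    group_length_ratios(means[PATHWAY_GROUPS])
  })

  inter <- stage("interactions",
                 interaction_count_summary(inputs$interactions,
                                           inputs$catalog))

  manifest <- data.frame(
    key = c("package_version", "seed", "human_species_id", "rescue",
            "threshold", "failure_prob", "rep_rule", "ss_type", "corr_unit",
            "input_dir", "n_species", "n_anchors", "n_proteins"),
    value = c(as.character(utils::packageVersion("repairome")),
              config$seed, config$human_species_id, config$rescue,
              config$threshold, config$failure_prob, config$rep_rule,
              config$ss_type, config$corr_unit,
              config$input_dir %||% "<synthetic>",
              nrow(inputs$species), nrow(inputs$catalog),
              nrow(inputs$proteins)),
    stringsAsFactors = FALSE)

  result <- list(inputs = inputs, family_map = fam, matrix = mat,
                 audit = audit, preservation = pres,
                 preservation_by_species = pres_sp,
                 preservation_by_pathway = pres_pw,
                 preservation_by_lifestyle_group = pres_lg,
                 repertoire = rep_size, heatmap = heat,
                 architectures = arch, decomposition = decomp,
                 profile = profile, correlations = corr, anova = anovas,
                 ratios = ratios, interaction_summary = inter,
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_tsv_strict(mat, file.path(out, "presence_length_matrix.tsv"))
    write_tsv_strict(pres, file.path(out, "preservation.tsv"))
    write_tsv_strict(pres_sp, file.path(out, "preservation_by_species.tsv"))
    write_tsv_strict(pres_pw, file.path(out, "preservation_by_pathway.tsv"))
    write_tsv_strict(pres_lg,
                     file.path(out, "preservation_by_lifestyle_group.tsv"))
    write_tsv_strict(rep_size, file.path(out, "ddr_repertoire.tsv"))
    write_tsv_strict(heat, file.path(out, "heatmap.tsv"))
    write_tsv_strict(arch, file.path(out, "architectures.tsv"))
    write_tsv_strict(decomp, file.path(out, "decomposition.tsv"))
    write_tsv_strict(corr, file.path(out, "correlations.tsv"))
    write_tsv_strict(anovas, file.path(out, "anova.tsv"))
    write_tsv_strict(ratios, file.path(out, "length_ratios.tsv"))
    write_tsv_strict(audit, file.path(out, "audit.tsv"))
    write_tsv_strict(inter, file.path(out, "interaction_summary.tsv"))
    write_tsv_strict(manifest, file.path(out, "run_manifest.tsv"))
    say("wrote %d tables to %s", 15L, out)
  }
  invisible(result)
}
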