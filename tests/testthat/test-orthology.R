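# Hand-built micro-fixture shared by several blocks: 3 species (human + two
# queries), two anchors, one orthogroup missing spQ so rescue has work to do.
micro_fixture <- function() {
  species <- data.frame(
    species_id = c("hum", "spR", "spQ"),
    display_name = c("Human", "Reference", "Query"),
    lifestyle = c("free_living", "free_living", "cytoplasmic"),
    organelle_status = c("atp_mito_or_plastid", "atp_mito_or_plastid",
                         "no_atp_mito"),
    clade = "c1", clade_reference = "spR",
    excluded_absences = FALSE, stringsAsFactors = FALSE)
  catalog <- data.frame(anchor_id = c("hA", "hB"),
                        pathway = "p1", pathway_group = "DDR",
                        stringsAsFactors = FALSE)
  proteins <- data.frame(
    species_id = c("hum", "hum", "spR", "spR", "spQ", "spQ", "spQ"),
    accession = c("hA", "hB", "spR_1", "spR_2", "spX9", "spQ_a", "spQ_b"),
    length = c(400L, 300L, 410L, 310L, 512L, 300L, 420L),
    stringsAsFactors = FALSE)
  orthogroups <- data.frame(
    orthogroup_id = c("OG1", "OG1", "OG2", "OG2", "OG2", "OG2"),
    species_id = c("hum", "spR", "hum", "spR", "spQ", "spQ"),
    accession = c("hA", "spR_1", "hB", "spR_2", "spQ_a", "spQ_b"),
    stringsAsFactors = FALSE)
  pairs <- data.frame(orthogroup_id = "OG1", species_a = "spR",
                      species_b = "spQ", gene_a = "spR_1", gene_b = "spX9",
                      stringsAsFactors = FALSE)
  ref_orth <- data.frame(reference_species = "spR", anchor_id = "hA",
                         reference_accession = "spR_1",
                         stringsAsFactors = FALSE)
  list(species = species, catalog = catalog, proteins = proteins,
       orthogroups = orthogroups, pairs = pairs, ref_orth = ref_orth)
}

test_that("family map assigns anchors to their orthogroups, NA when absent", {
  fx <- micro_fixture()
  cat2 <- rbind(fx$catalog,
                data.frame(anchor_id = "hC", pathway = "p1",
                           pathway_group = "DDR", stringsAsFactors = FALSE))
  fam <- build_family_map(fx$orthogroups, cat2, "hum")
  expect_equal(fam$orthogroup_id[fam$anchor_id == "hA"], "OG1")
  expect_equal(fam$orthogroup_id[fam$anchor_id == "hB"], "OG2")
  expect_true(is.na(fam$orthogroup_id[fam$anchor_id == "hC"]))
})

test_that("presence matrix applies the max-length representative rule", {
  fx <- micro_fixture()
  fam <- build_family_map(fx$orthogroups, fx$catalog, "hum")
  mat <- build_presence_matrix(fam, fx$orthogroups, fx$proteins, fx$species)
  # spQ has two in-paralogues of hB (300 and 420)
  row <- mat[mat$anchor_id == "hB" & mat$species_id == "spQ", ]
  expect_equal(row$status, "present")
  expect_equal(row$representative_length, 420)
  expect_equal(row$representative_accession, "spQ_b")
  expect_equal(row$n_copies, 2L)
  # mean rule behind the switch
  matm <- build_presence_matrix(fam, fx$orthogroups, fx$proteins, fx$species,
                                rep_rule = "mean")
  expect_equal(matm$representative_length[matm$anchor_id == "hB" &
                                          matm$species_id == "spQ"], 360)
  # hA has no spQ member -> absent
  expect_equal(mat$status[mat$anchor_id == "hA" & mat$species_id == "spQ"],
               "absent")
  # unmapped anchor is absent in every species
  cat2 <- rbind(fx$catalog,
                data.frame(anchor_id = "hC", pathway = "p1",
                           pathway_group = "DDR", stringsAsFactors = FALSE))
  fam2 <- build_family_map(fx$orthogroups, cat2, "hum")
  mat2 <- build_presence_matrix(fam2, fx$orthogroups, fx$proteins,
                                fx$species)
  expect_true(all(mat2$status[mat2$anchor_id == "hC"] == "absent"))
})

test_that("unresolvable accessions are reported with species and accession", {
  fx <- micro_fixture()
  fam <- build_family_map(fx$orthogroups, fx$catalog, "hum")
  bad <- fx$proteins[fx$proteins$accession != "spQ_b", ]
  expect_error(build_presence_matrix(fam, fx$orthogroups, bad, fx$species),
               "spQ_b.*spQ")
})

test_that("bait rescue recovers the constructed miss with the paired length", {
  fx <- micro_fixture()
  fam <- build_family_map(fx$orthogroups, fx$catalog, "hum")
  mat <- build_presence_matrix(fam, fx$orthogroups, fx$proteins, fx$species)
  res <- rescue_missing(mat, fx$pairs, fx$species, fx$ref_orth, fx$proteins)
  row <- res[res$anchor_id == "hA" & res$species_id == "spQ", ]
  expect_equal(row$status, "present")
  expect_equal(row$provenance, "rescued")
  expect_equal(row$representative_length, 512)
  expect_equal(row$representative_accession, "spX9")
  # anchor without a confirmed reference orthologue stays absent:
  # drop the reference-orthology row and nothing changes
  none <- fx$ref_orth[0, ]
  res2 <- rescue_missing(mat, fx$pairs, fx$species, none, fx$proteins)
  expect_identical(res2, mat)
  # rescue is idempotent and never downgrades
  res3 <- rescue_missing(res, fx$pairs, fx$species, fx$ref_orth, fx$proteins)
  expect_identical(res3, res)
})

test_that("rescue on synthetic worlds recovers exactly the rescuable misses", {
  w <- generate_world(small_config(seed = 17, miss_rate = 0.15))
  fam <- build_family_map(w$orthogroups, w$catalog, "hsap")
  mat <- build_presence_matrix(fam, w$orthogroups, w$proteins, w$species)
  res <- rescue_missing(mat, w$pairs, w$species, w$reference_orthology,
                        w$proteins)
  rescued <- res[res$provenance == "rescued", c("anchor_id", "species_id")]
  planted <- w$truth[w$truth$rescuable, c("anchor_id", "species_id")]
  expect_setequal(paste(rescued$anchor_id, rescued$species_id),
                  paste(planted$anchor_id, planted$species_id))
  # statuses only ever move absent -> present; excluded rows untouched
  expect_true(all(mat$status[res$status == "absent"] == "absent"))
  expect_identical(res[mat$status == "excluded", ],
                   mat[mat$status == "excluded", ])
  expect_identical(res[mat$status == "present", ],
                   mat[mat$status == "present", ])
  # per-species presence counts are monotone non-decreasing
  before <- table(mat$species_id[mat$status == "present"])
  after <- table(res$species_id[res$status == "present"])
  expect_true(all(after[names(before)] >= before))
  # rescued representative lengths match the ground truth
  key <- paste(res$anchor_id, res$species_id)
  tkey <- paste(w$truth$anchor_id, w$truth$species_id)
  ridx <- which(res$provenance == "rescued")
  expect_equal(res$representative_length[ridx],
               w$truth$length[match(key[ridx], tkey)])
})

test_that("audit tail probabilities match closed cases and enumeration", {
  expect_equal(calling_failure_tail(10, 0, 0.3), 1)
  expect_equal(calling_failure_tail(10, 1, 0), 0)
  expect_equal(calling_failure_tail(4, 2, 0.5), 11 / 16)
  for (n in c(3, 5, 8)) for (f in c(0.045, 0.5)) for (k in 0:n)
    expect_equal(calling_failure_tail(n, k, f), p_fail_enum(n, k, f),
                 tolerance = 1e-12)
  expect_error(calling_failure_tail(4, 5, 0.5), "k must")
  expect_error(calling_failure_tail(4, 2, 1.5), "f must")
})

test_that("the conserved-group audit selects and scores anchors correctly", {
  # 1 anchor present in 9/10 species, another in 5/10
  mat <- data.frame(
    anchor_id = rep(c("a1", "a2"), each = 10),
    species_id = rep(sprintf("s%02d", 1:10), 2),
    status = c(rep("present", 9), "absent", rep(c("present", "absent"), 5)),
    stringsAsFactors = FALSE)
  aud <- audit_conserved_groups(mat, threshold = 0.85, failure_prob = 0.1)
  expect_equal(aud$anchor_id, "a1")
  expect_equal(aud$n_species, 10L)
  expect_equal(aud$n_absent, 1L)
  expect_equal(aud$p_fail, 1 - (0.9)^10)
  # excluded cells leave numerator and denominator
  mat$status[mat$anchor_id == "a1" & mat$species_id == "s10"] <- "excluded"
  aud2 <- audit_conserved_groups(mat, threshold = 0.85, failure_prob = 0.1)
  expect_equal(aud2$n_species, 9L)
  expect_equal(aud2$n_absent, 0L)
  expect_equal(aud2$p_fail, 1)
  expect_error(audit_conserved_groups(mat, threshold = 0), "threshold")
})
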