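test_that("a fixed seed reproduces the world exactly", {
  w1 <- generate_world(small_config(seed = 5))
  w2 <- generate_world(small_config(seed = 5))
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$proteins, w2$proteins)
  expect_identical(w1$pfam_hits, w2$pfam_hits)
  expect_identical(w1$pairs, w2$pairs)
  w3 <- generate_world(small_config(seed = 6))
  expect_false(identical(w1$truth$present, w3$truth$present))
})

test_that("adding a species does not reshuffle existing species", {
  w1 <- generate_world(small_config(seed = 5))
  cfg2 <- small_config(seed = 5,
                       n_species = c(free_living = 7, extracellular = 4,
                                     cytoplasmic = 3, intranuclear = 3))
  w2 <- generate_world(cfg2)
  shared <- w1$species$species_id
  t1 <- w1$truth[w1$truth$species_id %in% shared, ]
  t2 <- w2$truth[w2$truth$species_id %in% shared, ]
  expect_equal(t1[order(t1$anchor_id, t1$species_id), ],
               t2[order(t2$anchor_id, t2$species_id), ],
               ignore_attr = TRUE)
})

test_that("config invariants are enforced", {
  expect_error(small_config(miss_rate = 1.5))
  expect_error(small_config(footprint = c(DDR = 0.95, replication = 0.45,
                                          metabolic = 0.55,
                                          housekeeping = 0.6)),
               "coverage")
  expect_error(small_config(multipliers = c(DDR = -1, replication = 1.84,
                                            metabolic = 1.48,
                                            housekeeping = 1)))
})

test_that("q = 0 worlds need no rescue and full retention forces preservation 1", {
  w <- generate_world(small_config(seed = 11, miss_rate = 0))
  expect_equal(sum(w$truth$missed), 0L)
  fam <- build_family_map(w$orthogroups, w$catalog, "hsap")
  mat <- build_presence_matrix(fam, w$orthogroups, w$proteins, w$species)
  mat2 <- rescue_missing(mat, w$pairs, w$species, w$reference_orthology,
                         w$proteins)
  expect_identical(mat, mat2)

  r1 <- matrix(1, 4, 4, dimnames = list(
    c("free_living", "extracellular", "cytoplasmic", "intranuclear"),
    c("DDR", "replication", "metabolic", "housekeeping")))
  wfull <- generate_world(small_config(seed = 12, retention = r1,
                                       miss_rate = 0,
                                       include_excluded_species = FALSE))
  fam <- build_family_map(wfull$orthogroups, wfull$catalog, "hsap")
  mat <- build_presence_matrix(fam, wfull$orthogroups, wfull$proteins,
                               wfull$species)
  pres <- pathway_preservation(mat, wfull$catalog)
  expect_true(all(pres$preservation == 1))
})

test_that("emitted files pass their readers and match the in-memory world", {
  w <- generate_world(small_config(seed = 9))
  d <- withr::local_tempdir()
  write_world(w, d)
  back <- read_world(d)
  expect_identical(back$species, w$species)
  expect_identical(back$catalog, w$catalog)
  key <- function(d) d[order(d$orthogroup_id, d$species_id, d$accession), ]
  expect_equal(key(back$orthogroups), key(w$orthogroups),
               ignore_attr = TRUE)
  lb <- back$proteins$length[match(w$proteins$accession,
                                   back$proteins$protein_id)]
  expect_equal(lb, w$proteins$length)
  expect_equal(nrow(back$pfam_hits), nrow(w$pfam_hits))
  expect_identical(back$interactions, w$interactions)
  expect_identical(back$reference_orthology, w$reference_orthology)
})

test_that("planted misses are withheld from orthogroups but present in pairing files", {
  w <- generate_world(small_config(seed = 21, miss_rate = 0.2))
  misses <- w$truth[w$truth$missed, ]
  expect_gt(nrow(misses), 0L)
  og_key <- paste(w$orthogroups$species_id,
                  w$family$anchor_id[match(w$orthogroups$orthogroup_id,
                                           w$family$orthogroup_id)])
  expect_false(any(paste(misses$species_id, misses$anchor_id) %in% og_key))
  # every rescuable miss has a pairing row carrying its accessions
  resc <- misses[misses$rescuable, ]
  pair_key <- paste(w$pairs$species_b,
                    w$family$anchor_id[match(w$pairs$orthogroup_id,
                                             w$family$orthogroup_id)])
  expect_true(all(paste(resc$species_id, resc$anchor_id) %in% pair_key))
})

test_that("empirical presence converges to the retention matrix", {
  cfg <- world_config(seed = 31, include_excluded_species = FALSE,
                      miss_rate = 0)
  w <- generate_world(cfg)
  ts <- truth_summary(w)
  emp <- ts$empirical_presence
  exp_ret <- ts$expected_preservation
  n_sp <- table(factor(w$species$lifestyle,
                       c("free_living", "extracellular", "cytoplasmic",
                         "intranuclear")))
  n_sp["free_living"] <- n_sp["free_living"] - 1L  # anchor species excluded
  n_anchor <- table(factor(w$catalog$pathway_group,
                           c("DDR", "replication", "metabolic",
                             "housekeeping")))
  for (lf in rownames(emp)) for (g in colnames(emp)) {
    n <- as.numeric(n_sp[lf]) * as.numeric(n_anchor[g])
    se <- sqrt(exp_ret[lf, g] * (1 - exp_ret[lf, g]) / n)
    expect_lt(abs(emp[lf, g] - exp_ret[lf, g]), 4 * se + 1e-9)
  }
})

test_that("truth is internally consistent", {
  w <- generate_world(small_config(seed = 13))
  tr <- w$truth
  expect_true(all(tr$n_copies[tr$present] >= 1L))
  expect_true(all(is.na(tr$length[!tr$present])))
  expect_true(all(tr$length[tr$present] > 0))
  # representative length is the max over that anchor's copies
  pk <- paste(w$proteins$anchor_id, w$proteins$species_id)
  mx <- tapply(w$proteins$length, pk, max)
  tk <- paste(tr$anchor_id, tr$species_id)[tr$present]
  expect_equal(as.numeric(mx[tk]), as.numeric(tr$length[tr$present]))
  # domain hits stay within their protein
  plen <- w$proteins$length[match(w$pfam_hits$protein_id,
                                  w$proteins$accession)]
  expect_true(all(w$pfam_hits$envelope_start >= 1L))
  expect_true(all(w$pfam_hits$envelope_end <= plen))
})
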