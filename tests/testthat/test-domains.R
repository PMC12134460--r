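test_that("interval merging handles identity, overlap and bookends", {
  expect_equal(merge_intervals(data.frame(start = 5, end = 120)),
               data.frame(start = 5L, end = 120L))
  m <- merge_intervals(data.frame(start = c(1, 5), end = c(10, 20)))
  expect_equal(m, data.frame(start = 1L, end = 20L))
  expect_equal(sum(m$end - m$start + 1), 20)
  # bookended intervals coalesce, gapped ones do not
  expect_equal(nrow(merge_intervals(data.frame(start = c(1, 11),
                                               end = c(10, 20)))), 1L)
  expect_equal(nrow(merge_intervals(data.frame(start = c(1, 12),
                                               end = c(10, 20)))), 2L)
  expect_error(merge_intervals(data.frame(start = 10, end = 5)),
               "start > end")
  expect_error(merge_intervals(data.frame(start = 0, end = 5)), "1-based")
  expect_equal(nrow(merge_intervals(data.frame(start = integer(0),
                                               end = integer(0)))), 0L)
})

test_that("merged coverage equals the per-residue oracle on random sets", {
  set.seed(71)
  for (rep in 1:60) {
    len <- sample(50:2000, 1)
    k <- sample(1:60, 1)
    s <- sample.int(len, k, replace = TRUE)
    e <- pmin(len, s + sample(0:200, k, replace = TRUE))
    m <- merge_intervals(data.frame(start = s, end = e))
    expect_equal(sum(m$end - m$start + 1), coverage_count(s, e, len))
    # disjoint, sorted, in range
    expect_true(all(m$start <= m$end))
    if (nrow(m) > 1) expect_true(all(m$start[-1] > m$end[-nrow(m)] + 1))
  }
})

test_that("architectures decompose length exactly", {
  prot <- data.frame(protein_id = "p1", length = 200L)
  hits <- data.frame(protein_id = "p1",
                     envelope_start = c(1L, 151L), envelope_end = c(50L, 200L),
                     stringsAsFactors = FALSE)
  a <- domain_architecture(prot, hits)
  expect_equal(a$domain_length, 100L)
  expect_equal(a$interdomain_length, 100L)
  expect_equal(a$footprint, 0.5)
  expect_equal(a$n_domains, 2L)
  # no hits: footprint 0, interdomain = full length
  a0 <- domain_architecture(prot, hits[0, ])
  expect_equal(a0$domain_length, 0L)
  expect_equal(a0$interdomain_length, 200L)
  expect_equal(a0$footprint, 0)
  # out-of-range hit names the protein rather than clipping
  badhit <- data.frame(protein_id = "p1", envelope_start = 150L,
                       envelope_end = 230L, stringsAsFactors = FALSE)
  expect_error(domain_architecture(prot, badhit), "p1.*length 200")
})

test_that("bulk architecture table matches per-protein computation", {
  w <- generate_world(small_config(seed = 33))
  prot <- data.frame(protein_id = w$proteins$accession,
                     length = w$proteins$length, stringsAsFactors = FALSE)
  arch <- architecture_table(prot, w$pfam_hits)
  expect_equal(arch$domain_length + arch$interdomain_length,
               arch$protein_length)
  # spot-check 20 proteins against the single-protein path
  set.seed(1)
  for (i in sample(nrow(prot), 20)) {
    h <- w$pfam_hits[w$pfam_hits$protein_id == prot$protein_id[i], ]
    one <- domain_architecture(prot[i, ], h)
    expect_equal(arch[i, ], one, ignore_attr = TRUE)
  }
  # footprint is translation-invariant: shifting a whole architecture
  # within the protein leaves D (and footprint) unchanged
  h <- data.frame(protein_id = "q", envelope_start = c(11L, 61L),
                  envelope_end = c(30L, 90L), stringsAsFactors = FALSE)
  p <- data.frame(protein_id = "q", length = 300L)
  base <- domain_architecture(p, h)
  h2 <- h; h2$envelope_start <- h2$envelope_start + 100L
  h2$envelope_end <- h2$envelope_end + 100L
  shifted <- domain_architecture(p, h2)
  expect_equal(shifted$domain_length, base$domain_length)
  expect_equal(shifted$footprint, base$footprint)
})

test_that("group decomposition reduces to the protein for singleton cells", {
  arch <- data.frame(protein_id = c("a1", "b1"),
                     protein_length = c(200L, 400L),
                     n_domains = c(2L, 1L), n_segments = c(2L, 1L),
                     domain_length = c(100L, 240L),
                     interdomain_length = c(100L, 160L),
                     footprint = c(0.5, 0.6), stringsAsFactors = FALSE)
  mat <- data.frame(anchor_id = c("hA", "hB"), species_id = "sp1",
                    status = "present",
                    representative_length = c(200, 400),
                    representative_accession = c("a1", "b1"),
                    n_copies = 1L, provenance = "direct",
                    stringsAsFactors = FALSE)
  catalog <- data.frame(anchor_id = c("hA", "hB"),
                        pathway = c("p1", "p2"),
                        pathway_group = c("DDR", "housekeeping"),
                        stringsAsFactors = FALSE)
  species <- data.frame(species_id = "sp1", lifestyle = "free_living",
                        stringsAsFactors = FALSE)
  dec <- group_length_decomposition(arch, mat, catalog, species)
  ddr <- dec[dec$pathway_group == "DDR", ]
  expect_equal(ddr$mean_length, 200)
  expect_equal(ddr$mean_footprint, 0.5)
  expect_equal(ddr$domain_density, 2 / 100)
  expect_equal(ddr$domain_density_per_100, 2)
  # doubling a protein and its intervals leaves the footprint unchanged
  arch2 <- arch
  arch2$protein_length <- arch2$protein_length * 2L
  arch2$domain_length <- arch2$domain_length * 2L
  arch2$interdomain_length <- arch2$interdomain_length * 2L
  mat2 <- mat; mat2$representative_length <- mat2$representative_length * 2
  dec2 <- group_length_decomposition(arch2, mat2, catalog, species)
  expect_equal(dec2$mean_footprint, dec$mean_footprint)
})

test_that("length correlations recover forced monotone structure", {
  # I = length - constant D: rho(length, I) = 1; reversed ranks give -1
  prof <- data.frame(mean_length = c(100, 150, 220, 300, 410),
                     mean_domain_length = 80,
                     mean_interdomain_length = c(100, 150, 220, 300, 410) - 80)
  lc <- length_correlations(prof)
  expect_equal(lc$rho[lc$pair == "length~interdomain"], 1)
  expect_true(is.na(lc$rho[lc$pair == "length~domain"]))  # constant D
  prof2 <- data.frame(mean_length = 1:8,
                      mean_domain_length = 8:1,
                      mean_interdomain_length = 1:8)
  lc2 <- length_correlations(prof2)
  expect_equal(lc2$rho[lc2$pair == "length~domain"], -1)
  expect_equal(lc2$df, lc2$n - 2L)
  expect_error(length_correlations(prof2[1:2, ]), "at least 3")
})
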