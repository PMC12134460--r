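# Shared fixtures: a scaled-down synthetic world for fast unit tests, and
# small independent oracles used across test files.

small_config <- function(seed = 42, ...) {
  args <- list(
    seed = seed,
    n_species = c(free_living = 7, extracellular = 4, cytoplasmic = 3,
                  intranuclear = 2),
    pathway_sizes = list(
      DDR = c(nucleotide_excision_repair = 12,
              homologous_recombination = 10,
              checkpoint_factors = 8,
              nucleotide_pool_modulation = 6),
      replication = c(dna_replication = 8),
      metabolic = c(central_carbon_metabolism = 7),
      housekeeping = c(housekeeping_core = 6)),
    n_clades = 3)
  do.call(world_config, utils::modifyList(args, list(...)))
}

# per-residue boolean coverage: total residues covered by a set of 1-based
# inclusive intervals
coverage_count <- function(start, end, len) {
  covered <- logical(len)
  for (i in seq_along(start)) covered[start[i]:end[i]] <- TRUE
  sum(covered)
}

# exhaustive enumeration of P(#failures >= k) over all 2^n outcomes
p_fail_enum <- function(n, k, f) {
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  pr <- apply(grid, 1L, function(x) prod(ifelse(x == 1L, f, 1 - f)))
  sum(pr[rowSums(grid) >= k])
}

# average ranks computed from first principles (sort, then average the
# positions of equal values)
avg_ranks <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  pos <- 1L
  while (pos <= length(x)) {
    tiegrp <- which(x[o] == x[o[pos]])
    r[o[tiegrp]] <- mean(tiegrp)
    pos <- max(tiegrp) + 1L
  }
  r
}

# Pearson correlation from raw sums (independent of stats::cor)
pearson_sums <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}
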