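# Shared fixtures: small simulation configs and convenience runners used
# across the test files. All fixtures are generated in code.

small_sim_config <- function(seed = 7L, ...) {
  defaults <- list(
    n_genes = 400L, modulon_size = 60L,
    condition_private_deg_count = 30L, n_regulons = 12L,
    regulon_size_range = c(5L, 16L), planted_enriched_regulons = 3L,
    seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# a single-condition all-null config (no planted signal, full 5-point grid)
null_sim_config <- function(seed, n_genes = 250L) {
  simulation_config(
    n_genes = n_genes, conditions = "phosphate",
    modulon_size = 0L, condition_private_deg_count = 0L,
    dropped_samples = data.frame(condition = character(0),
                                 replicate = integer(0),
                                 mu = numeric(0)),
    n_regulons = 10L, seed = seed)
}

# fit all conditions and call DEGs with shipped defaults
fit_all_conditions <- function(sim, family = "auto") {
  m <- suppressMessages(drop_all_zero_genes(sim$counts))
  sf <- rle_size_factors(m)
  conds <- unique(sim$meta$condition)
  fits <- lapply(conds, function(cc) {
    fit_profiles(m, sim$meta, cc, size_factors = sf, family = family)
  })
  names(fits) <- conds
  degs <- lapply(fits, call_degs)
  names(degs) <- conds
  list(m = m, sf = sf, fits = fits, degs = degs)
}

# plain-R adjusted Rand index used when mclust is unavailable
simple_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    mclust::adjustedRandIndex(a, b)
  } else {
    simple_ari(a, b)
  }
}
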