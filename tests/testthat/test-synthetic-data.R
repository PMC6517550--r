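test_that("profile templates anchor at the reference rate with the four shapes", {
  grid <- c(0, 0.1, 0.2, 0.3, 0.4)
  tpl <- make_profile_templates(grid, 1.5)
  expect_equal(dim(tpl), c(4L, 5L))
  # all anchored to 0 at the reference
  expect_equal(unname(tpl[, 5]), rep(0, 4))
  # cluster 1: monotone increase toward the reference, span = amplitude
  expect_true(all(diff(tpl[1, ]) > 0))
  expect_equal(unname(tpl[1, 1]), -1.5)
  # cluster 2: flat over the lower half, then sharp increase
  expect_equal(unname(tpl[2, 1:3]), rep(-1.5, 3))
  expect_true(all(diff(tpl[2, 3:5]) > 0))
  expect_gt(tpl[2, 5] - tpl[2, 4], tpl[1, 5] - tpl[1, 4])
  # cluster 3: rises to a peak at the second-highest rate, then falls
  expect_true(all(diff(tpl[3, 1:4]) > 0))
  expect_lt(tpl[3, 5], tpl[3, 4])
  # cluster 4: strictly decreasing toward the reference in every interval
  expect_true(all(diff(tpl[4, ]) < 0))
  expect_error(make_profile_templates(c(0, 0.4), 1), "3")
})

test_that("cluster-1 span tracks the amplitude across the stated range", {
  for (a in c(1, 1.5, 2)) {
    tpl <- make_profile_templates(c(0, 0.1, 0.2, 0.3, 0.4), a)
    expect_equal(unname(tpl[1, 5] - tpl[1, 1]), a)
    expect_true(all(diff(tpl[4, ]) < 0))
  }
})

test_that("simulation config enforces its invariants", {
  expect_error(simulation_config(n_genes = -5), "integer")
  expect_error(simulation_config(n_genes = 10.5), "integer")
  expect_error(simulation_config(cluster_proportions = c(.5, .5, .1, 0)),
               "summing to 1")
  expect_error(simulation_config(modulon_size = 3000L,
                                 condition_private_deg_count = 500L),
               "exceeds")
  expect_error(simulation_config(
    dropped_samples = data.frame(condition = "iron", replicate = 1L,
                                 mu = 0.1)), "outside the design")
  expect_error(simulation_config(regulon_size_range = c(10L, 5000L)),
               "exceeds n_genes")
})

test_that("the default design enumerates to 40 samples, matching the study layout", {
  cfg <- simulation_config(n_genes = 50L, modulon_size = 0L,
                           condition_private_deg_count = 0L)
  sim <- simulate_counts(cfg)
  # independent enumeration: full factorial minus drops
  full <- expand.grid(condition = cfg$conditions,
                      replicate = 1:3, mu = cfg$mu_grid,
                      stringsAsFactors = FALSE)
  drops <- default_dropped_samples()
  key <- function(d) paste(d$condition, d$replicate, d$mu)
  expected_n <- nrow(full) - sum(key(full) %in% key(drops))
  expect_equal(expected_n, 40L)
  expect_equal(ncol(sim$counts), expected_n)
  expect_equal(nrow(sim$meta), expected_n)
  # no carbon samples at mu = 0; the two rejected replicates are absent
  expect_false(any(sim$meta$condition == "carbon" & sim$meta$mu == 0))
  expect_false(any(sim$meta$condition == "carbon" &
                     sim$meta$replicate == 2 & sim$meta$mu == 0.1))
  expect_false(any(sim$meta$condition == "nitrogen" &
                     sim$meta$replicate == 3 & sim$meta$mu == 0.2))
  # metadata triples unique, ids match the count matrix
  expect_false(any(duplicated(sim$meta[c("condition", "replicate", "mu")])))
  expect_identical(sim$meta$sample_id, colnames(sim$counts))
})

test_that("simulation is bit-reproducible for a fixed seed", {
  cfg <- small_sim_config(seed = 123L)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(unclass(s1$counts), unclass(s2$counts))
  expect_identical(s1$truth$modulon_genes, s2$truth$modulon_genes)
  n1 <- simulate_network(cfg, s1$truth)
  n2 <- simulate_network(cfg, s2$truth)
  expect_identical(n1, n2)
  # a different seed changes the draw
  s3 <- simulate_counts(small_sim_config(seed = 124L))
  expect_false(identical(unclass(s1$counts), unclass(s3$counts)))
})

test_that("ground truth is internally consistent", {
  sim <- simulate_counts(small_sim_config(seed = 5L))
  truth <- sim$truth
  expect_setequal(names(truth$cluster_of_gene), truth$modulon_genes)
  expect_true(all(truth$cluster_of_gene %in% 1:4))
  # private DEGs never overlap the modulon
  expect_length(
    intersect(unlist(truth$private_deg_genes), truth$modulon_genes), 0)
  # modulon genes carry the same template in every condition: their mean
  # profile at shared rates is identical across conditions
  mp <- truth$mean_profile
  g <- truth$modulon_genes[1]
  prof <- mp[mp$gene == g & mp$mu %in% c(0.1, 0.2, 0.3, 0.4), ]
  by_cond <- split(prof$log2_rel[order(prof$mu)], prof$condition[order(prof$mu)])
  expect_equal(by_cond$phosphate, by_cond$nitrogen)
  expect_equal(by_cond$phosphate, by_cond$carbon)
})

test_that("modulon_size = 0 yields a null model with flat truth", {
  cfg <- small_sim_config(seed = 9L, modulon_size = 0L,
                          condition_private_deg_count = 0L)
  sim <- simulate_counts(cfg)
  expect_length(sim$truth$modulon_genes, 0)
  expect_null(sim$truth$mean_profile)
})

test_that("counts are non-negative integers with library sizes in range", {
  cfg <- small_sim_config(seed = 11L,
                          library_size_range = c(2e5, 8e5))
  sim <- simulate_counts(cfg)
  x <- unclass(sim$counts)
  expect_true(all(x >= 0))
  expect_true(all(x == round(x)))
  libs <- colSums(x)
  # observed totals concentrate near their expectation
  expect_true(all(libs > 2e5 * 0.9 & libs < 8e5 * 1.1))
})

test_that("count law matches the negative-binomial variance model", {
  # 200 replicate samples at one rate, fixed library size: each gene is a
  # set of iid NB draws whose variance must track m + phi * m^2
  phi <- 0.1
  cfg <- simulation_config(
    n_genes = 300L, conditions = "phosphate", mu_grid = c(0, 0.2, 0.4),
    replicates_per_point = 67L,
    dropped_samples = data.frame(condition = character(0),
                                 replicate = integer(0), mu = numeric(0)),
    modulon_size = 0L, condition_private_deg_count = 0L,
    nb_dispersion = phi, library_size_range = c(1e6, 1e6),
    n_regulons = 2L, regulon_size_range = c(2L, 5L),
    planted_enriched_regulons = 0L, seed = 31L)
  sim <- simulate_counts(cfg)
  x <- unclass(sim$counts)
  m_hat <- rowMeans(x)
  v_hat <- apply(x, 1, var)
  keep <- m_hat > 20
  expect_gt(sum(keep), 200)
  ratio <- v_hat[keep] / (m_hat[keep] + phi * m_hat[keep]^2)
  # per-gene variance ratios centre on 1 (201 df each); the median over
  # >200 genes is within a few standard errors of 1
  expect_lt(abs(median(ratio) - 1), 0.05)
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("network planting puts the promised fraction of targets in the modulon", {
  cfg <- small_sim_config(seed = 13L, planted_modulon_fraction = 0.6)
  sim <- simulate_counts(cfg)
  net <- simulate_network(cfg, sim$truth)
  expect_false(any(duplicated(paste(net$regulator, net$target))))
  planted <- attr(net, "enriched_regulators")
  expect_length(planted, 3)
  regs <- regulons_from_network(net)
  for (r in planted) {
    frac <- mean(regs[[r]] %in% sim$truth$modulon_genes)
    expect_gte(frac, 0.5)
  }
  # planted fraction is exact by construction for a known size
  r1 <- regs[[planted[1]]]
  k_in <- sum(r1 %in% sim$truth$modulon_genes)
  expect_equal(k_in, max(ceiling(length(r1) / 2), round(0.6 * length(r1))))
})

test_that("without planting no regulon has majority-modulon targets", {
  cfg <- small_sim_config(seed = 17L, planted_enriched_regulons = 0L)
  sim <- simulate_counts(cfg)
  net <- simulate_network(cfg, sim$truth)
  expect_length(attr(net, "enriched_regulators"), 0)
  fracs <- vapply(regulons_from_network(net), function(tg) {
    mean(tg %in% sim$truth$modulon_genes)
  }, numeric(1))
  expect_true(all(fracs < 0.5))
})

test_that("ground truth round-trips through JSON", {
  sim <- simulate_counts(small_sim_config(seed = 19L))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth_json(sim$truth, path)
  back <- read_ground_truth_json(path)
  expect_setequal(back$modulon_genes, sim$truth$modulon_genes)
  expect_equal(back$cluster_of_gene[sim$truth$modulon_genes],
               sim$truth$cluster_of_gene[sim$truth$modulon_genes])
})
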