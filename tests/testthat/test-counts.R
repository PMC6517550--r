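toy_counts <- function(x, genes = NULL, samples = NULL) {
  m <- matrix(as.integer(x), nrow = length(x) / 2)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  count_matrix(m)
}

test_that("count_matrix validates counts and identifiers", {
  expect_error(count_matrix(matrix(1:4, 2)), "rownames")
  m <- matrix(c(1, -1, 2, 3), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(count_matrix(m), "non-negative")
  m <- matrix(c(1.5, 1, 2, 3), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(count_matrix(m), "integers")
})

test_that("RLE size factors reproduce the median-of-ratios definition", {
  # two identical samples -> unit factors
  m <- toy_counts(c(5, 9, 5, 9))
  expect_equal(unname(rle_size_factors(m)), c(1, 1))
  # hand-computed 2x2 case: geometric means (sqrt(16), sqrt(128));
  # per-sample ratios are 1/sqrt(2) and sqrt(2) for every gene
  m <- count_matrix(matrix(c(2L, 8L, 4L, 16L), 2,
                           dimnames = list(c("g1", "g2"), c("s1", "s2"))))
  sf <- rle_size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # scaling one sample by 10 scales only its factor by 10
  set.seed(8)
  x <- matrix(rpois(60, 50) + 1L, 10,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:6)))
  m1 <- count_matrix(x)
  x2 <- x; x2[, 3] <- x[, 3] * 10L
  m2 <- count_matrix(x2)
  f1 <- rle_size_factors(m1); f2 <- rle_size_factors(m2)
  # geometric means shift by 10^(1/6); all factors pick that up, sample 3
  # additionally by 10
  expect_equal(unname(f2[3] / f1[3] / (f2[1] / f1[1])), 10,
               tolerance = 1e-10)
  expect_error(rle_size_factors(toy_counts(c(0, 3, 2, 0))), "pseudo")
})

test_that("RLE has the median-of-ratios fixed point on random matrices", {
  set.seed(21)
  for (i in 1:5) {
    x <- matrix(rnbinom(200 * 8, mu = exp(rnorm(200, 4, 1)), size = 10),
                200, 8, dimnames = list(sprintf("g%d", 1:200),
                                        sprintf("s%d", 1:8)))
    m <- suppressMessages(drop_all_zero_genes(count_matrix(x)))
    sf <- rle_size_factors(m)
    norm <- normalize_counts(m, sf)
    ref <- rownames(m)[rowSums(unclass(m) > 0) == ncol(m)]
    loggeo <- rowMeans(log(unclass(m)[ref, ]))
    for (j in seq_len(ncol(m))) {
      expect_equal(median(log(norm[ref, j]) - loggeo), 0,
                   tolerance = 1e-10)
    }
  }
})

test_that("RLE agrees with the DESeq2 median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(33)
  x <- matrix(rnbinom(500 * 10, mu = exp(rnorm(500, 4, 1.2)), size = 8),
              500, 10, dimnames = list(sprintf("g%d", 1:500),
                                       sprintf("s%d", 1:10)))
  m <- suppressMessages(drop_all_zero_genes(count_matrix(x)))
  expect_equal(unname(rle_size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(unclass(m))),
               tolerance = 1e-8)
})

test_that("Poisson dissimilarity is zero on matched samples, symmetric, non-negative", {
  # duplicated samples with equal factors fit the null exactly
  m <- toy_counts(c(4, 7, 13, 4, 7, 13), samples = c("a", "b"))
  d <- poisson_dissimilarity(m, factors = c(a = 1, b = 1))
  expect_equal(unname(d["a", "b"]), 0)
  # proportional columns with ratio equal to the factor ratio
  m <- toy_counts(c(2, 5, 9, 6, 15, 27), samples = c("a", "b"))
  d <- poisson_dissimilarity(m, factors = c(a = 1, b = 3))
  expect_equal(unname(d["a", "b"]), 0, tolerance = 1e-12)
  # same columns under equal factors are NOT null -> positive distance
  d2 <- poisson_dissimilarity(m, factors = c(a = 1, b = 1))
  expect_gt(d2["a", "b"], 0)
  # symmetry, zero diagonal, non-negativity on random data
  set.seed(14)
  x <- matrix(rpois(50 * 5, 30), 50, 5,
              dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:5)))
  d3 <- poisson_dissimilarity(count_matrix(x))
  expect_equal(unclass(d3), t(unclass(d3)))
  expect_equal(unname(diag(d3)), rep(0, 5))
  expect_true(all(d3 >= 0))
})

test_that("Poisson dissimilarity matches a term-by-term oracle on a 3-gene toy", {
  m <- toy_counts(c(4, 0, 2, 0, 4, 2), samples = c("a", "b"))
  d <- poisson_dissimilarity(m, factors = c(a = 1, b = 1))
  # independent evaluation, gene by gene, of the deviance formula
  oracle <- 0
  x <- unclass(m)
  for (g in 1:3) {
    pooled <- (x[g, 1] + x[g, 2]) / 2
    for (j in 1:2) {
      xi <- x[g, j]
      oracle <- oracle +
        (if (xi > 0) xi * log(xi / pooled) else 0) - (xi - pooled)
    }
  }
  expect_equal(unname(d["a", "b"]), oracle, tolerance = 1e-12)
})

test_that("sample clustering recovers separated groups and ignores input order", {
  # constructed dissimilarity: two tight groups far apart
  ids <- sprintf("s%d", 1:6)
  d <- matrix(10, 6, 6, dimnames = list(ids, ids))
  d[1:3, 1:3] <- 1; d[4:6, 4:6] <- 1; diag(d) <- 0
  cl <- cluster_samples(d, k = 2)
  expect_length(unique(cl$clusters[1:3]), 1)
  expect_length(unique(cl$clusters[4:6]), 1)
  expect_false(cl$clusters[1] == cl$clusters[4])
  # permutation invariance of the flat clusters
  perm <- c(4, 2, 6, 1, 3, 5)
  cl2 <- cluster_samples(d[perm, perm], k = 2)
  expect_equal(ari(cl$clusters[ids], cl2$clusters[ids]), 1)
  expect_warning(cluster_samples(d[1, 1, drop = FALSE]), "single")
})

test_that("counts, metadata and dendrograms round-trip through files", {
  sim <- simulate_counts(small_sim_config(seed = 3L, n_genes = 80L,
                                          modulon_size = 10L,
                                          condition_private_deg_count = 5L))
  cpath <- withr::local_tempfile(fileext = ".tsv")
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(sim$counts, cpath)
  write_sample_meta_tsv(sim$meta, mpath)
  m2 <- read_counts_tsv(cpath)
  expect_identical(unclass(m2), unclass(sim$counts))
  meta2 <- read_sample_meta_tsv(mpath)
  expect_equal(meta2$sample_id, sim$meta$sample_id)
  expect_equal(meta2$mu, sim$meta$mu)
  d <- poisson_dissimilarity(suppressMessages(drop_all_zero_genes(sim$counts)))
  cl <- cluster_samples(d)
  npath <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl$tree, npath)
  tr <- ape::read.tree(npath)
  expect_setequal(tr$tip.label, colnames(sim$counts))
})
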