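# Count-matrix container, RLE (median-of-ratios) size factors, Poisson
# model-based sample dissimilarity, and hierarchical sample clustering.

#' Construct a count matrix
#'
#' Thin validated wrapper around a genes x samples matrix of non-negative
#' integer read counts with unique row (gene) and column (sample) names.
#'
#' @param counts Numeric matrix, genes in rows, samples in columns, with
#'   dimnames.
#' @return A matrix of class `count_matrix`.
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("gene and sample ids must be unique")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_matrix", class(counts))
  counts
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples, total %.3g reads\n",
              nrow(x), ncol(x), sum(as.numeric(x))))
  invisible(x)
}

#' Drop genes with zero counts in every sample
#'
#' All-zero genes carry no information, break per-gene geometric means, and
#' are removed (with a message) before normalization.
#'
#' @param m A [count_matrix()].
#' @return Filtered `count_matrix`.
#' @export
drop_all_zero_genes <- function(m) {
  keep <- rowSums(m) > 0
  if (!all(keep)) {
    message(sprintf("dropping %d all-zero gene(s)", sum(!keep)))
    m <- count_matrix(unclass(m)[keep, , drop = FALSE])
  }
  m
}

#' Relative log expression (median-of-ratios) size factors
#'
#' The per-gene geometric mean across samples defines a pseudo-reference
#' sample; each sample's size factor is the median, over genes with
#' positive counts in every sample, of the ratio of its counts to the
#' reference. Dividing counts by the factors puts samples on a common
#' scale.
#'
#' @param m A [count_matrix()] (or plain matrix).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
rle_size_factors <- function(m) {
  logc <- log(unclass(m))
  ref <- rownames(m)[apply(is.finite(logc), 1, all)]
  if (length(ref) == 0) {
    stop("no gene has positive counts in every sample; ",
         "cannot form the RLE pseudo-reference (filter samples or genes)")
  }
  loggeo <- rowMeans(logc[ref, , drop = FALSE])
  sf <- apply(logc[ref, , drop = FALSE], 2,
              function(col) exp(stats::median(col - loggeo)))
  stats::setNames(sf, colnames(m))
}

#' Normalize counts by size factors
#'
#' @param m A [count_matrix()].
#' @param factors Size factors from [rle_size_factors()].
#' @return Numeric matrix of normalized counts (not integer).
#' @export
normalize_counts <- function(m, factors = rle_size_factors(m)) {
  if (ncol(m) != length(factors)) stop("one size factor per sample required")
  sweep(unclass(m), 2, factors, `/`)
}

# Poisson deviance of observed x against expected m, with 0*log(0) := 0
poisson_deviance_terms <- function(x, m) {
  t1 <- ifelse(x > 0, x * log(x / m), 0)
  t1 - (x - m)
}

#' Poisson model-based sample dissimilarity
#'
#' For each sample pair (i, j) the null model states that both columns
#' share one relative-abundance profile, scaled by their size factors; the
#' expected count of gene g in sample i is then
#' `s_i (x_gi + x_gj) / (s_i + s_j)`. The dissimilarity is the total
#' Poisson deviance of the observed counts against this null:
#' \deqn{d(i,j) = \sum_g x_{gi}\log(x_{gi}/m_{gi}) - (x_{gi}-m_{gi})
#'              + x_{gj}\log(x_{gj}/m_{gj}) - (x_{gj}-m_{gj})}
#' It is zero exactly when the two columns are proportional with ratio
#' equal to the ratio of their size factors. A square-root transform of the
#' counts is available as a variance-stabilizing option.
#'
#' @param m A [count_matrix()].
#' @param factors Size factors; default RLE.
#' @param transform `"none"` (default) or `"sqrt"`.
#' @return Symmetric sample x sample matrix with zero diagonal, class
#'   `dissimilarity_matrix`.
#' @export
poisson_dissimilarity <- function(m, factors = rle_size_factors(m),
                                  transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  if (ncol(m) != length(factors)) {
    stop("one size factor per sample required")
  }
  x <- unclass(m)
  storage.mode(x) <- "double"
  if (transform == "sqrt") x <- sqrt(x)
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      si <- factors[i]; sj <- factors[j]
      pooled <- (x[, i] + x[, j]) / (si + sj)
      mi <- si * pooled
      mj <- sj * pooled
      keep <- pooled > 0
      d[i, j] <- d[j, i] <-
        sum(poisson_deviance_terms(x[keep, i], mi[keep])) +
        sum(poisson_deviance_terms(x[keep, j], mj[keep]))
    }
  }
  d[d < 0] <- 0  # guard tiny negative round-off
  class(d) <- c("dissimilarity_matrix", class(d))
  d
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of a sample dissimilarity matrix. Leaf order is
#' deterministic given the input order; cutting the tree reports flat
#' clusters.
#'
#' @param d A `dissimilarity_matrix` (or symmetric matrix / `dist`).
#' @param linkage `"complete"` (default), `"average"`, `"ward.D2"`, or
#'   `"single"`.
#' @param k Optional number of flat clusters to cut.
#' @return List with `tree` (an [stats::hclust] object), `leaf_order`
#'   (sample ids in dendrogram order), and, when `k` is given, `clusters`
#'   (named integer vector).
#' @export
cluster_samples <- function(d, linkage = c("complete", "average",
                                           "ward.D2", "single"),
                            k = NULL) {
  linkage <- match.arg(linkage)
  if (inherits(d, "dissimilarity_matrix") || is.matrix(d)) {
    if (nrow(d) == 1) {
      warning("single sample: trivial one-leaf tree")
      return(list(tree = NULL, leaf_order = rownames(d),
                  clusters = stats::setNames(1L, rownames(d))))
    }
    d <- stats::as.dist(d)
  }
  tree <- stats::hclust(d, method = linkage)
  out <- list(tree = tree, leaf_order = tree$labels[tree$order])
  if (!is.null(k)) out$clusters <- stats::cutree(tree, k = k)
  out
}

#' Export a sample dendrogram in Newick format
#'
#' @param tree An [stats::hclust] object (e.g. from [cluster_samples()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Read/write count matrices and sample metadata as TSV
#'
#' Counts: first column `gene_id`, one column per sample. Metadata: columns
#' `sample_id`, `condition`, `replicate`, `mu`, `time_h`.
#'
#' @param m A [count_matrix()]; `meta` a metadata data frame.
#' @param path File path.
#' @param meta Sample metadata data frame.
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @export
write_counts_tsv <- function(m, path) {
  d <- data.frame(gene_id = rownames(m), unclass(m), check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (names(d)[1] != "gene_id") stop("first column must be gene_id")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  count_matrix(m)
}

#' @rdname write_counts_tsv
#' @export
write_sample_meta_tsv <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_sample_meta_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "replicate", "mu")
  if (!all(need %in% names(d))) {
    stop("metadata TSV needs columns: ", paste(need, collapse = ", "))
  }
  d
}

#' Write a dissimilarity matrix as TSV
#'
#' @param d Dissimilarity matrix.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_dissimilarity_tsv <- function(d, path) {
  out <- data.frame(sample_id = rownames(d), unclass(d),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
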