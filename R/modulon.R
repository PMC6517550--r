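# Growth-modulon identification: intersection of per-condition DEG sets,
# cross-condition profile-similarity filtering, and 4-way profile
# clustering on a Pearson-correlation distance.

#' Intersect per-condition DEG sets
#'
#' @param deg_sets List of `deg_set` objects (or plain character vectors),
#'   one per condition; at least two.
#' @return List with `genes` (the exact intersection) and
#'   `overlap_fractions` (per condition, |shared| / |condition DEGs|).
#' @export
intersect_degs <- function(deg_sets) {
  if (length(deg_sets) < 2) stop("need DEG sets from at least 2 conditions")
  sets <- lapply(deg_sets, function(s) {
    if (inherits(s, "deg_set")) s$genes else as.character(s)
  })
  nms <- names(sets)
  if (is.null(nms)) {
    nms <- vapply(seq_along(deg_sets), function(i) {
      if (inherits(deg_sets[[i]], "deg_set")) deg_sets[[i]]$condition
      else paste0("set", i)
    }, character(1))
  }
  shared <- Reduce(intersect, sets)
  frac <- vapply(sets, function(s) {
    if (length(s) == 0) NA_real_ else length(intersect(shared, s)) / length(s)
  }, numeric(1))
  list(genes = shared, overlap_fractions = stats::setNames(frac, nms))
}

# extract a gene's fitted log2fc vector over a mu grid from a fit table
fit_log2fc_row <- function(fits, gene) {
  i <- match(gene, fits$gene_id)
  if (is.na(i)) return(NULL)
  cols <- grep("^log2fc_", names(fits), value = TRUE)
  unlist(fits[i, cols], use.names = FALSE)
}

#' Cross-condition profile similarity of one gene
#'
#' Evaluates each condition's fitted log2 fold-change profile on the common
#' growth-rate grid and returns the minimum, over condition pairs, of the
#' Pearson correlation of the two profile vectors. Near-flat profiles
#' (range below `flat_eps` in any condition) make correlations meaningless
#' and yield `NA`.
#'
#' @param profiles List (one element per condition) of numeric log2
#'   fold-change vectors on a common grid.
#' @param flat_eps Flat-profile guard in log2 units (default 0.1).
#' @return Minimum pairwise Pearson correlation in \[-1, 1\], or `NA`.
#' @export
profile_similarity <- function(profiles, flat_eps = 0.1) {
  if (length(profiles) < 2) stop("need profiles from at least 2 conditions")
  lens <- vapply(profiles, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("profiles must be evaluated on a common grid")
  }
  if (any(vapply(profiles, function(p) diff(range(p)) < flat_eps,
                 logical(1)))) {
    return(NA_real_)
  }
  pairs <- utils::combn(length(profiles), 2)
  min(apply(pairs, 2, function(ij) {
    stats::cor(profiles[[ij[1]]], profiles[[ij[2]]])
  }))
}

# log2fc profiles of `gene` in each condition, restricted to the common grid
common_grid_profiles <- function(fits_per_condition, gene) {
  grids <- lapply(fits_per_condition, attr, "mu_grid")
  common <- Reduce(intersect, grids)
  if (length(common) < 3) stop("common growth-rate grid has < 3 points")
  out <- lapply(seq_along(fits_per_condition), function(i) {
    v <- fit_log2fc_row(fits_per_condition[[i]], gene)
    if (is.null(v)) return(NULL)
    v[match(common, grids[[i]])]
  })
  names(out) <- names(fits_per_condition)
  if (any(vapply(out, is.null, logical(1)))) return(NULL)
  out
}

#' Identify the growth modulon
#'
#' The modulon is the subset of genes differentially expressed in every
#' condition whose fitted expression profiles are similar across all
#' conditions: the minimum pairwise Pearson correlation of the fitted
#' log2 fold-change profiles (evaluated on the growth rates shared by all
#' conditions) must reach `similarity_threshold`. Genes with a near-flat
#' profile in any condition, or without a fit in some condition, are
#' excluded and logged.
#'
#' @param deg_sets Named list of `deg_set` objects, one per condition.
#' @param fits_per_condition Named list of `profile_fit_table`s matching
#'   `deg_sets`.
#' @param similarity_threshold Minimum pairwise profile correlation in
#'   (-1, 1\]; default 0.7.
#' @param flat_eps Flat-profile guard passed to [profile_similarity()].
#' @return Object of class `modulon_result`: list with
#'   `intersection_genes`, `modulon_genes`, `similarity_score` (named, per
#'   intersection gene; `NA` for flat/missing), `similarity_threshold`,
#'   `cluster_of_gene` (unset until [cluster_profiles()]),
#'   `mean_cluster_profiles` (unset), `overlap_fractions`.
#' @export
identify_modulon <- function(deg_sets, fits_per_condition,
                             similarity_threshold = 0.7, flat_eps = 0.1) {
  if (similarity_threshold > 1) stop("similarity threshold must be <= 1")
  inter <- intersect_degs(deg_sets)
  if (length(inter$genes) == 0) {
    warning("empty DEG intersection: modulon is empty")
  }
  score <- vapply(inter$genes, function(g) {
    prof <- common_grid_profiles(fits_per_condition, g)
    if (is.null(prof)) return(NA_real_)
    profile_similarity(prof, flat_eps = flat_eps)
  }, numeric(1))
  names(score) <- inter$genes
  keep <- !is.na(score) & score >= similarity_threshold
  n_na <- sum(is.na(score))
  if (n_na > 0) {
    message(sprintf(
      "%d intersection gene(s) excluded (flat profile or missing fit)",
      n_na))
  }
  structure(
    list(intersection_genes = inter$genes,
         modulon_genes = inter$genes[keep],
         similarity_score = score,
         similarity_threshold = similarity_threshold,
         cluster_of_gene = NULL,
         mean_cluster_profiles = NULL,
         overlap_fractions = inter$overlap_fractions),
    class = "modulon_result")
}

#' @export
print.modulon_result <- function(x, ...) {
  cat(sprintf(
    "modulon_result: %d intersection genes -> %d modulon genes (min pairwise r >= %g)\n",
    length(x$intersection_genes), length(x$modulon_genes),
    x$similarity_threshold))
  if (!is.null(x$cluster_of_gene)) {
    cat("cluster sizes:",
        paste(table(x$cluster_of_gene), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cluster modulon genes by expression profile
#'
#' Concatenates each modulon gene's fitted log2 fold-change profiles over
#' all conditions, computes a 1 - Pearson-correlation distance between
#' genes, clusters agglomeratively, and cuts the tree at `k` (default 4).
#' Cluster labels are renumbered so that semantics are stable across runs:
#' clusters are ordered by decreasing Pearson correlation of their mean
#' profile with the growth rate, i.e. cluster 1 rises most steadily with
#' growth rate and cluster k falls.
#'
#' @param result A `modulon_result` from [identify_modulon()].
#' @param fits_per_condition Named list of `profile_fit_table`s.
#' @param k Number of profile clusters (default 4).
#' @param linkage Agglomeration rule (default `"complete"`).
#' @return The `modulon_result` with `cluster_of_gene` (named integer
#'   vector over modulon genes) and `mean_cluster_profiles` (matrix k x
#'   concatenated-grid of per-cluster average log2 fold changes) filled in.
#' @export
cluster_profiles <- function(result, fits_per_condition, k = 4,
                             linkage = "complete") {
  stopifnot(inherits(result, "modulon_result"))
  genes <- result$modulon_genes
  if (k > length(genes)) {
    stop("k exceeds the number of modulon genes")
  }
  profs <- t(vapply(genes, function(g) {
    unlist(lapply(fits_per_condition, fit_log2fc_row, gene = g),
           use.names = FALSE)
  }, numeric(sum(vapply(fits_per_condition, function(f)
    length(grep("^log2fc_", names(f))), integer(1))))))
  rownames(profs) <- genes
  mu_concat <- unlist(lapply(fits_per_condition, attr, "mu_grid"),
                      use.names = FALSE)
  d <- stats::as.dist(1 - stats::cor(t(profs)))
  tree <- stats::hclust(d, method = linkage)
  raw <- stats::cutree(tree, k = k)
  means <- t(vapply(seq_len(k), function(cl) {
    colMeans(profs[raw == cl, , drop = FALSE])
  }, numeric(ncol(profs))))
  # stable semantics: order clusters by decreasing correlation of the mean
  # profile with growth rate (1 = steady rise ... k = fall)
  shape <- apply(means, 1, function(p) {
    if (stats::sd(p) == 0) 0 else stats::cor(p, mu_concat)
  })
  relabel <- match(seq_len(k), order(shape, decreasing = TRUE))
  clusters <- stats::setNames(relabel[raw], genes)
  means <- means[order(shape, decreasing = TRUE), , drop = FALSE]
  rownames(means) <- seq_len(k)
  colnames(means) <- paste0(
    rep(names(fits_per_condition),
        vapply(fits_per_condition, function(f)
          length(grep("^log2fc_", names(f))), integer(1))),
    "_mu", mu_concat)
  result$cluster_of_gene <- clusters
  result$mean_cluster_profiles <- means
  result$cluster_tree <- tree
  result
}

#' Write modulon outputs
#'
#' `write_modulon_tsv` writes one row per modulon gene (gene, similarity
#' score, cluster); `write_overlap_table_tsv` writes, for every gene in any
#' DEG set, its per-condition membership (Venn/UpSet-ready).
#'
#' @param result A `modulon_result`.
#' @param path File path.
#' @param deg_sets Named list of `deg_set` objects.
#' @return `path`, invisibly.
#' @export
write_modulon_tsv <- function(result, path) {
  genes <- result$modulon_genes
  d <- data.frame(
    gene_id = genes,
    similarity_score = unname(result$similarity_score[genes]),
    cluster = if (is.null(result$cluster_of_gene)) NA_integer_
              else unname(result$cluster_of_gene[genes]),
    stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_modulon_tsv
#' @export
write_overlap_table_tsv <- function(deg_sets, path) {
  sets <- lapply(deg_sets, function(s) {
    if (inherits(s, "deg_set")) s$genes else as.character(s)
  })
  all_genes <- sort(unique(unlist(sets)))
  d <- data.frame(gene_id = all_genes, stringsAsFactors = FALSE)
  for (nm in names(sets)) d[[nm]] <- as.integer(all_genes %in% sets[[nm]])
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
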