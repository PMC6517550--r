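# Hypergeometric over-representation of regulons and gene sets within the
# modulon, with Benjamini-Hochberg control, plus regulatory-network and
# gene-set (GMT) file handling and network export.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ hypergeometric(N, K, n): the probability of drawing at
#' least `k` marked items when `n` items are drawn without replacement from
#' a universe of `N` items of which `K` are marked. Terms are accumulated
#' in log space (via `lchoose`) for numerical stability; P(X >= 0) = 1.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K Number of marked items (set size).
#' @param n Number of draws (e.g. modulon size).
#' @param N Universe size.
#' @return Probability in (0, 1\].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) != round(c(k, K, n, N))) || any(c(k, K, n, N) < 0)) {
    stop("k, K, n, N must be non-negative integers")
  }
  if (K > N || n > N || k > min(K, n)) {
    stop("inconsistent counts: need k <= min(K, n), K <= N, n <= N")
  }
  if (k == 0) return(1)
  i <- seq(k, min(K, n))
  lo <- max(0, n - (N - K))
  if (k <= lo) return(1)
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(logp)
  min(exp(mx + log(sum(exp(logp - mx)))), 1)
}

#' Read a regulator -> target edge list
#'
#' Tab-separated with columns regulator and target; lines starting with `#`
#' are comments. Duplicate edges are removed with a message.
#'
#' @param path File path.
#' @return Data frame with columns `regulator`, `target`.
#' @export
read_network_tsv <- function(path) {
  d <- utils::read.delim(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("network TSV needs regulator and target columns")
  names(d)[1:2] <- c("regulator", "target")
  d <- d[, c("regulator", "target")]
  dup <- duplicated(paste(d$regulator, d$target))
  if (any(dup)) {
    message(sprintf("removed %d duplicate edge(s)", sum(dup)))
    d <- d[!dup, , drop = FALSE]
    rownames(d) <- NULL
  }
  d
}

#' @rdname read_network_tsv
#' @param edges Data frame with columns `regulator`, `target`.
#' @export
write_network_tsv <- function(edges, path) {
  utils::write.table(edges[, c("regulator", "target")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write GMT gene-set files
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path File path.
#' @param sets Named list of character vectors (for writing).
#' @param descriptions Optional character vector of set descriptions.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Regulons of a network
#'
#' @param edges Edge data frame (`regulator`, `target`).
#' @return Named list: regulator -> character vector of targets.
#' @export
regulons_from_network <- function(edges) {
  split(edges$target, edges$regulator)
}

#' Hypergeometric over-representation of gene sets in the modulon
#'
#' Tests every set (intersected with the universe first) for
#' over-representation among the modulon genes with the one-sided
#' upper-tail hypergeometric test, then applies Benjamini-Hochberg control
#' across all tested sets. Sets with fewer than `min_set_size` genes in the
#' universe are skipped. When `cluster_of_gene` is given, the overlap of
#' each set is broken down by profile cluster.
#'
#' @param modulon Character vector of modulon gene ids (within `universe`).
#' @param sets Named list of gene sets (regulons or pathways).
#' @param universe Character vector: the gene universe (all genes tested
#'   for differential expression, i.e. those in the count matrix after the
#'   all-zero filter).
#' @param alpha Significance level on adjusted p (default 0.05).
#' @param min_set_size Minimum in-universe set size to test (default 2).
#' @param cluster_of_gene Optional named integer vector mapping modulon
#'   genes to profile clusters 1..4.
#' @return Data frame (class `enrichment_table`), one row per tested set,
#'   sorted by adjusted p: `set_id`, `k` (set genes in the modulon), `K`
#'   (in-universe set size), `n` (modulon size), `N` (universe size),
#'   `p_value`, `p_adjusted`, `significant`, and `cluster1..cluster4`
#'   columns when cluster labels are supplied.
#' @export
enrich_sets <- function(modulon, sets, universe, alpha = 0.05,
                        min_set_size = 2, cluster_of_gene = NULL) {
  if (length(universe) == 0) stop("empty universe")
  if (length(sets) == 0) stop("empty set collection")
  universe <- unique(universe)
  unknown <- setdiff(modulon, universe)
  if (length(unknown) > 0) {
    message(sprintf("%d modulon gene(s) outside the universe ignored",
                    length(unknown)))
    modulon <- intersect(modulon, universe)
  }
  N <- length(universe)
  n <- length(modulon)
  rows <- lapply(names(sets), function(id) {
    set <- intersect(unique(sets[[id]]), universe)
    K <- length(set)
    if (K < min_set_size) return(NULL)
    overlap <- intersect(set, modulon)
    k <- length(overlap)
    row <- data.frame(set_id = id, k = k, K = K, n = n, N = N,
                      p_value = hypergeom_upper_tail(k, K, n, N),
                      stringsAsFactors = FALSE)
    attr(row, "overlap_genes") <- overlap
    row
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    stop("no set has >= ", min_set_size, " genes in the universe")
  }
  overlaps <- lapply(rows, attr, "overlap_genes")
  out <- do.call(rbind, rows)
  out$p_adjusted <- benjamini_hochberg(out$p_value)
  out$significant <- out$p_adjusted < alpha
  if (!is.null(cluster_of_gene)) {
    bd <- t(vapply(overlaps, function(g) {
      cluster_breakdown(g, cluster_of_gene)
    }, numeric(4)))
    colnames(bd) <- paste0("cluster", 1:4)
    out <- cbind(out, bd)
  }
  o <- order(out$p_adjusted, out$p_value, out$set_id)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "overlap_genes") <- stats::setNames(overlaps[o], out$set_id)
  attr(out, "alpha") <- alpha
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Per-cluster breakdown of an overlap
#'
#' Counts how many of the overlap genes fall in each profile cluster 1-4;
#' the counts sum to the overlap size.
#'
#' @param overlap_genes Character vector of genes (set intersected with the
#'   modulon).
#' @param cluster_of_gene Named integer vector mapping modulon genes to
#'   clusters 1..4.
#' @return Integer vector of length 4.
#' @export
cluster_breakdown <- function(overlap_genes, cluster_of_gene) {
  if (length(overlap_genes) == 0) return(rep(0L, 4))
  cl <- cluster_of_gene[overlap_genes]
  if (any(is.na(cl))) {
    stop("overlap gene(s) without a cluster label: ",
         paste(overlap_genes[is.na(cl)], collapse = ", "))
  }
  tabulate(cl, nbins = 4)
}

#' Export the significant regulator-gene network
#'
#' Writes a SIF-style edge list restricted to significant regulators and
#' their modulon targets, plus a node-attribute table (node type and, for
#' genes, profile cluster). The edge file round-trips through
#' [read_network_tsv()].
#'
#' @param rows An `enrichment_table` from [enrich_sets()].
#' @param edges Full network edge data frame (`regulator`, `target`).
#' @param modulon Character vector of modulon genes.
#' @param cluster_of_gene Named integer vector of cluster labels.
#' @param edge_path,node_path Output file paths.
#' @return Invisible list with the exported `edges` and `nodes` data
#'   frames.
#' @export
export_network <- function(rows, edges, modulon, cluster_of_gene,
                           edge_path, node_path) {
  sig <- rows$set_id[rows$significant]
  sub <- edges[edges$regulator %in% sig & edges$target %in% modulon, ,
               drop = FALSE]
  rownames(sub) <- NULL
  write_network_tsv(sub, edge_path)
  nodes <- rbind(
    data.frame(node_id = sig,
               type = rep("regulator", length(sig)),
               cluster = rep(NA_integer_, length(sig)),
               stringsAsFactors = FALSE),
    if (nrow(sub) > 0) {
      tg <- sort(unique(sub$target))
      data.frame(node_id = tg, type = "gene",
                 cluster = as.integer(cluster_of_gene[tg]),
                 stringsAsFactors = FALSE)
    })
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(edges = sub, nodes = nodes))
}

#' Write an enrichment table as TSV
#'
#' Columns mirror a regulon-enrichment overview table: set id, overlap and
#' set sizes, per-cluster counts when available, and raw/adjusted
#' p-values.
#'
#' @param rows An `enrichment_table`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(rows, path) {
  utils::write.table(as.data.frame(rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
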