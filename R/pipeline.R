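# End-to-end orchestration: simulate/load -> growth kinetics -> normalize &
# cluster samples -> per-condition DE -> modulon -> enrichment, with a YAML
# config and a JSON run manifest.

pipeline_defaults <- function() {
  list(
    outdir = NULL,
    seed = 1L,
    simulate = TRUE,
    inputs = list(counts = NULL, meta = NULL, network = NULL,
                  gene_sets = NULL),
    simulation = list(),   # overrides for simulation_config()
    kinetics = list(
      enabled = TRUE,
      viabilities = c(phosphate = 60, nitrogen = 96, carbon = 88),
      lag_h = c(phosphate = 4, nitrogen = 10, carbon = 1),
      mu_max = 0.4, ramp_h = 6, noise_sd = 0,
      targets = c(0, 0.1, 0.2, 0.3, 0.4)),
    clustering = list(linkage = "complete", transform = "none"),
    de = list(alpha = 0.05, lfc_cutoffs = default_lfc_cutoffs(),
              family = "auto"),
    modulon = list(similarity_threshold = 0.7, k = 4, flat_eps = 0.1,
                   linkage = "complete"),
    enrichment = list(alpha = 0.05, min_set_size = 2,
                      pathway_alpha = 0.025)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]])) && nm != "simulation" &&
        nm != "lfc_cutoffs" && nm != "viabilities" && nm != "lag_h") {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    } else {
      v <- user[[nm]]
      if (is.list(v) && all(vapply(v, length, integer(1)) == 1) &&
          !is.null(names(v)) && nm != "simulation" && nm != "inputs") {
        v <- unlist(v)
      }
      defaults[[nm]] <- v
    }
  }
  defaults
}

#' Build a pipeline run configuration
#'
#' Merges user settings over the pipeline defaults; unknown keys are
#' rejected so typos fail loudly. Settings can come from a YAML file
#' (`run_config_from_yaml()`) or an R list.
#'
#' @param ... Named settings (see the pipeline vignette): `outdir`, `seed`,
#'   `simulate`, `inputs`, `simulation`, `kinetics`, `clustering`, `de`,
#'   `modulon`, `enrichment`.
#' @param path Path to a YAML config file.
#' @return Object of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(pipeline_defaults(), user)
  if (is.null(cfg$outdir)) stop("config must set `outdir`")
  cfg$seed <- as.integer(cfg$seed)
  # YAML sequences arrive as lists; flatten plain numeric/character ones
  flatten <- function(v) {
    if (is.list(v) && length(v) > 0 &&
        all(vapply(v, function(x) is.atomic(x) && length(x) == 1,
                   logical(1)))) unlist(v) else v
  }
  cfg$kinetics$targets <- flatten(cfg$kinetics$targets)
  cfg$simulation <- lapply(cfg$simulation, flatten)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @export
run_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

stage_fail <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage,
               conditionMessage(e)), call. = FALSE)
}

#' Run the full growth-modulon pipeline
#'
#' Executes, in order: data simulation (or loading of counts, metadata and
#' network files), growth-kinetics estimation on simulated viability
#' curves, RLE normalization with Poisson-dissimilarity sample clustering,
#' per-condition cubic-profile differential expression, modulon
#' identification with 4-way profile clustering, and regulon (plus
#' optional GMT gene-set) over-representation. All stage outputs are
#' written under `config$outdir` together with a JSON manifest recording
#' every parameter, input checksums, and per-stage row counts. Reruns with
#' an identical config reproduce identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisible list with the in-memory stage results (`simulation`,
#'   `kinetics`, `sample_clustering`, `fits`, `degs`, `modulon`,
#'   `enrichment`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  manifest <- list(parameters = unclass(config),
                   seed = config$seed, stages = list())
  results <- list()

  # -- stage 1: data ---------------------------------------------------
  stage <- "data"
  res <- tryCatch({
    if (isTRUE(config$simulate)) {
      sim_args <- config$simulation
      sim_args$seed <- config$seed
      scfg <- do.call(simulation_config, sim_args)
      sim <- simulate_counts(scfg)
      net <- simulate_network(scfg, sim$truth)
      sim$truth$enriched_regulators <- attr(net, "enriched_regulators")
      sim$network <- net
      write_counts_tsv(sim$counts, out("counts.tsv"))
      write_sample_meta_tsv(sim$meta, out("sample_meta.tsv"))
      write_network_tsv(net, out("network.tsv"))
      write_ground_truth_json(sim$truth, out("ground_truth.json"))
      sim
    } else {
      need <- c("counts", "meta", "network")
      miss <- need[vapply(need, function(k)
        is.null(config$inputs[[k]]) || !file.exists(config$inputs[[k]]),
        logical(1))]
      if (length(miss) > 0) {
        stop("missing input file(s): ",
             paste(unlist(config$inputs[miss]), collapse = ", "))
      }
      list(counts = read_counts_tsv(config$inputs$counts),
           meta = read_sample_meta_tsv(config$inputs$meta),
           network = read_network_tsv(config$inputs$network),
           truth = NULL)
    }
  }, error = function(e) stage_fail(stage, e))
  results$simulation <- res
  counts <- drop_all_zero_genes(res$counts)
  manifest$stages$data <- list(
    n_genes = nrow(counts), n_samples = ncol(counts),
    n_edges = nrow(res$network), simulated = isTRUE(config$simulate))

  # -- stage 2: growth kinetics ---------------------------------------
  if (isTRUE(config$kinetics$enabled)) {
    stage <- "kinetics"
    results$kinetics <- tryCatch({
      conds <- unique(res$meta$condition)
      kin <- lapply(conds, function(cc) {
        kc <- config$kinetics
        v <- if (cc %in% names(kc$viabilities)) kc$viabilities[[cc]] else 100
        lag <- if (cc %in% names(kc$lag_h)) kc$lag_h[[cc]] else 2
        gs <- simulate_growth_curve(v, lag_h = lag, mu_max = kc$mu_max,
                                    noise_sd = kc$noise_sd,
                                    ramp_h = kc$ramp_h, condition = cc)
        ms <- mu_differential(gs)
        write_growth_curve_tsv(gs, out(paste0("growth_", cc, ".tsv")))
        write_mu_tsv(ms, out(paste0("mu_", cc, ".tsv")))
        cand <- data.frame(sample_id = sprintf("%s_t%02d", cc,
                             seq_along(ms$interval_midpoint_time)),
                           time = ms$interval_midpoint_time)
        sel <- suppressWarnings(
          select_samples(cand, ms, config$kinetics$targets))
        utils::write.table(sel, out(paste0("selection_", cc, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        list(series = gs, mu = ms, selection = sel)
      })
      names(kin) <- conds
      kin
    }, error = function(e) stage_fail(stage, e))
    manifest$stages$kinetics <- list(
      conditions = names(results$kinetics),
      n_targets = length(config$kinetics$targets))
  }

  # -- stage 3: normalization & sample clustering ---------------------
  stage <- "sample_clustering"
  results$sample_clustering <- tryCatch({
    sf <- rle_size_factors(counts)
    d <- poisson_dissimilarity(counts, sf,
                               transform = config$clustering$transform)
    cl <- cluster_samples(d, linkage = config$clustering$linkage)
    write_dissimilarity_tsv(d, out("dissimilarity.tsv"))
    write_dendrogram_newick(cl$tree, out("sample_dendrogram.nwk"))
    list(size_factors = sf, dissimilarity = d, clustering = cl)
  }, error = function(e) stage_fail(stage, e))
  sf <- results$sample_clustering$size_factors
  manifest$stages$sample_clustering <- list(
    n_samples = ncol(counts), linkage = config$clustering$linkage)

  # -- stage 4: differential expression -------------------------------
  stage <- "differential_expression"
  conds <- unique(res$meta$condition)
  de <- tryCatch({
    fits <- lapply(conds, function(cc) {
      f <- fit_profiles(counts, res$meta, cc, size_factors = sf,
                        family = config$de$family)
      write_profile_fits_tsv(f, out(paste0("fits_", cc, ".tsv")))
      f
    })
    names(fits) <- conds
    degs <- lapply(conds, function(cc) {
      cut <- if (cc %in% names(config$de$lfc_cutoffs)) {
        config$de$lfc_cutoffs[[cc]]
      } else NULL
      dg <- call_degs(fits[[cc]], alpha = config$de$alpha,
                      log2fc_cutoff = cut)
      write_deg_list(dg, out(paste0("degs_", cc, ".txt")))
      dg
    })
    names(degs) <- conds
    list(fits = fits, degs = degs)
  }, error = function(e) stage_fail(stage, e))
  results$fits <- de$fits
  results$degs <- de$degs
  manifest$stages$differential_expression <- list(
    alpha = config$de$alpha,
    deg_counts = lapply(de$degs, function(d) length(d$genes)))

  # -- stage 5: modulon ------------------------------------------------
  stage <- "modulon"
  results$modulon <- tryCatch({
    mr <- identify_modulon(
      de$degs, de$fits,
      similarity_threshold = config$modulon$similarity_threshold,
      flat_eps = config$modulon$flat_eps)
    if (length(mr$modulon_genes) >= config$modulon$k) {
      mr <- cluster_profiles(mr, de$fits, k = config$modulon$k,
                             linkage = config$modulon$linkage)
    }
    write_modulon_tsv(mr, out("modulon.tsv"))
    write_overlap_table_tsv(de$degs, out("deg_overlap.tsv"))
    if (!is.null(mr$mean_cluster_profiles)) {
      utils::write.table(
        data.frame(cluster = rownames(mr$mean_cluster_profiles),
                   mr$mean_cluster_profiles, check.names = FALSE),
        out("cluster_mean_profiles.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    mr
  }, error = function(e) stage_fail(stage, e))
  manifest$stages$modulon <- list(
    intersection = length(results$modulon$intersection_genes),
    modulon = length(results$modulon$modulon_genes),
    k = config$modulon$k)

  # -- stage 6: enrichment --------------------------------------------
  stage <- "enrichment"
  results$enrichment <- tryCatch({
    universe <- rownames(counts)
    regulons <- regulons_from_network(res$network)
    et <- enrich_sets(results$modulon$modulon_genes, regulons, universe,
                      alpha = config$enrichment$alpha,
                      min_set_size = config$enrichment$min_set_size,
                      cluster_of_gene = results$modulon$cluster_of_gene)
    write_enrichment_tsv(et, out("regulon_enrichment.tsv"))
    exp <- export_network(et, res$network,
                          results$modulon$modulon_genes,
                          results$modulon$cluster_of_gene,
                          out("grn_edges.tsv"), out("grn_nodes.tsv"))
    pw <- NULL
    if (!is.null(config$inputs$gene_sets) &&
          file.exists(config$inputs$gene_sets %||% "")) {
      gmt <- read_gmt(config$inputs$gene_sets)
      pw <- enrich_sets(results$modulon$modulon_genes, gmt, universe,
                        alpha = config$enrichment$pathway_alpha,
                        min_set_size = config$enrichment$min_set_size)
      write_enrichment_tsv(pw, out("pathway_enrichment.tsv"))
    }
    list(regulons = et, pathways = pw, network_export = exp)
  }, error = function(e) stage_fail(stage, e))
  manifest$stages$enrichment <- list(
    tested = nrow(results$enrichment$regulons),
    significant = sum(results$enrichment$regulons$significant))

  # -- manifest --------------------------------------------------------
  files <- list.files(config$outdir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$input_checksums <- as.list(tools::md5sum(files))
  names(manifest$input_checksums) <- basename(files)
  manifest$completed_stages <- names(manifest$stages)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
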