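# Synthetic emulation of a three-condition growth-rate-transition RNA-Seq
# study: negative-binomial counts over a mu-indexed design with a planted
# modulon, condition-private DEGs, and planted enriched regulons.

#' Default dropped samples of the emulated design
#'
#' The emulated design has three pre-culture conditions (phosphate,
#' nitrogen, carbon) sampled at target growth rates 0-0.4 1/h in three
#' biological replicates. Carbon-limited cultures resume growth too quickly
#' to be sampled at mu = 0, and two replicates (C2 at mu = 0.1, N3 at
#' mu = 0.2) fail quality assessment, leaving 40 samples.
#'
#' @return Data frame with columns `condition`, `replicate`, `mu`.
#' @export
default_dropped_samples <- function() {
  data.frame(
    condition = c("carbon", "carbon", "carbon", "carbon", "nitrogen"),
    replicate = c(1L, 2L, 3L, 2L, 3L),
    mu = c(0, 0, 0, 0.1, 0.2),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles all parameters of the synthetic-data generator and validates
#' them. Defaults emulate a three-condition transition experiment: 3
#' pre-culture conditions x growth
#' rates \{0, 0.1, 0.2, 0.3, 0.4\} 1/h x 3 replicates, minus the samples in
#' [default_dropped_samples()] (40 samples), ~3,000 genes, a planted
#' 400-gene modulon split over four profile shapes, and 5 planted enriched
#' regulons among 50.
#'
#' @param n_genes Number of genes.
#' @param conditions Condition labels.
#' @param mu_grid Growth-rate grid (1/h), ascending; the last element is the
#'   reference rate for log2 fold changes.
#' @param replicates_per_point Biological replicates per (condition, mu).
#' @param dropped_samples Data frame of (condition, replicate, mu) triples
#'   removed from the full factorial design.
#' @param modulon_size Number of planted modulon genes (same profile shape
#'   in every condition).
#' @param cluster_proportions Four non-negative fractions summing to 1:
#'   share of modulon genes in each profile cluster.
#' @param amplitude_log2 Effect size of the planted profiles (log2 units;
#'   span between the extreme and the reference rate).
#' @param nb_dispersion Negative-binomial dispersion phi
#'   (variance = m + phi m^2); 0 gives Poisson counts.
#' @param library_size_range Min/max expected total counts per sample;
#'   library sizes are drawn log-uniformly in this range.
#' @param condition_private_deg_count Genes differentially expressed in only
#'   one or two conditions (flat elsewhere); these must not enter the
#'   modulon.
#' @param n_regulons Number of regulons in the simulated network.
#' @param regulon_size_range Min/max regulon size.
#' @param planted_enriched_regulons Number of regulons whose targets are
#'   drawn preferentially from the modulon.
#' @param planted_modulon_fraction Fraction of a planted regulon's targets
#'   inside the modulon (>= 0.5).
#' @param seed Integer RNG seed; fixed seed gives bit-identical output.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 3000L,
                              conditions = c("phosphate", "nitrogen",
                                             "carbon"),
                              mu_grid = c(0, 0.1, 0.2, 0.3, 0.4),
                              replicates_per_point = 3L,
                              dropped_samples = default_dropped_samples(),
                              modulon_size = 400L,
                              cluster_proportions = rep(0.25, 4),
                              amplitude_log2 = 1.5,
                              nb_dispersion = 0.05,
                              library_size_range = c(5e5, 2e6),
                              condition_private_deg_count = 150L,
                              n_regulons = 50L,
                              regulon_size_range = c(5L, 30L),
                              planted_enriched_regulons = 5L,
                              planted_modulon_fraction = 0.6,
                              seed = 1L) {
  chk_count <- function(x, name, min = 0) {
    if (length(x) != 1 || !is.numeric(x) || !is.finite(x) ||
        x != round(x) || x < min) {
      stop(sprintf("`%s` must be an integer >= %d", name, min))
    }
  }
  chk_count(n_genes, "n_genes", 1)
  chk_count(replicates_per_point, "replicates_per_point", 1)
  chk_count(modulon_size, "modulon_size", 0)
  chk_count(condition_private_deg_count, "condition_private_deg_count", 0)
  chk_count(n_regulons, "n_regulons", 1)
  chk_count(planted_enriched_regulons, "planted_enriched_regulons", 0)
  chk_count(seed, "seed")
  if (length(cluster_proportions) != 4 || any(cluster_proportions < 0) ||
      abs(sum(cluster_proportions) - 1) > 1e-9) {
    stop("`cluster_proportions` must be 4 non-negative fractions summing to 1")
  }
  if (amplitude_log2 < 0) stop("`amplitude_log2` must be non-negative")
  if (nb_dispersion < 0) stop("`nb_dispersion` must be non-negative")
  if (length(library_size_range) != 2 || any(library_size_range <= 0) ||
      diff(library_size_range) < 0) {
    stop("`library_size_range` must be positive (min, max)")
  }
  if (length(regulon_size_range) != 2 ||
      any(regulon_size_range != round(regulon_size_range)) ||
      regulon_size_range[1] < 1 || diff(regulon_size_range) < 0) {
    stop("`regulon_size_range` must be integer (min, max), min >= 1")
  }
  if (regulon_size_range[2] > n_genes) {
    stop("requested regulon size exceeds n_genes")
  }
  if (planted_modulon_fraction < 0.5 || planted_modulon_fraction > 1) {
    stop("`planted_modulon_fraction` must be in [0.5, 1]")
  }
  if (planted_enriched_regulons > n_regulons) {
    stop("more planted regulons than regulons")
  }
  if (is.unsorted(mu_grid, strictly = TRUE)) {
    stop("`mu_grid` must be strictly ascending")
  }
  if (modulon_size + condition_private_deg_count > n_genes) {
    stop("modulon_size + condition_private_deg_count exceeds n_genes")
  }
  if (nrow(dropped_samples) > 0) {
    ok <- dropped_samples$condition %in% conditions &
      dropped_samples$replicate %in% seq_len(replicates_per_point) &
      vapply(dropped_samples$mu,
             function(m) any(abs(m - mu_grid) < 1e-9), logical(1))
    if (!all(ok)) {
      stop("dropped_samples refer to (condition, replicate, mu) outside the design")
    }
  }
  structure(
    list(n_genes = as.integer(n_genes), conditions = conditions,
         mu_grid = mu_grid,
         replicates_per_point = as.integer(replicates_per_point),
         dropped_samples = dropped_samples,
         modulon_size = as.integer(modulon_size),
         cluster_proportions = cluster_proportions,
         amplitude_log2 = amplitude_log2, nb_dispersion = nb_dispersion,
         library_size_range = library_size_range,
         condition_private_deg_count =
           as.integer(condition_private_deg_count),
         n_regulons = as.integer(n_regulons),
         regulon_size_range = as.integer(regulon_size_range),
         planted_enriched_regulons = as.integer(planted_enriched_regulons),
         planted_modulon_fraction = planted_modulon_fraction,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Evaluate one cluster template at normalized grid positions s in [0, 1]
# (s = 1 is the reference rate). peak_s: position of the cluster-3 maximum.
template_value <- function(cluster, s, amplitude, peak_s) {
  switch(cluster,
    # steady rise toward the reference
    `1` = -amplitude * (1 - s),
    # flat at low rates, sharp rise over the upper half
    `2` = ifelse(s <= 0.5, -amplitude, -2 * amplitude * (1 - s)),
    # rise to a peak at the second-to-last rate, then fall to the reference
    `3` = ifelse(s <= peak_s,
                 -amplitude + (1.5 * amplitude) * s / peak_s,
                 0.5 * amplitude * (1 - s) / (1 - peak_s)),
    # monotone fall toward the reference
    `4` = amplitude * (1 - s),
    stop("cluster must be 1..4")
  )
}

#' Planted expression-profile templates
#'
#' Returns the four log2 fold-change profile shapes planted by the
#' generator, evaluated on a growth-rate grid and anchored to 0 at the
#' reference (highest) rate: (1) steady increase with growth rate, (2) flat
#' at low rates then sharply increasing over the upper half, (3) increasing
#' to a peak at the second-highest rate then decreasing, (4) steady
#' decrease. The amplitude is the log2 span between the extreme value and
#' the reference.
#'
#' @param mu_grid Ascending growth-rate grid (>= 3 points); the last element
#'   is the reference.
#' @param amplitude_log2 Profile amplitude in log2 units.
#' @return 4 x length(mu_grid) matrix of log2 fold changes; rows are
#'   clusters 1-4, columns named by growth rate.
#' @export
make_profile_templates <- function(mu_grid, amplitude_log2) {
  if (length(mu_grid) < 3) {
    stop("need at least 3 growth-rate grid points to define profile shapes")
  }
  if (is.unsorted(mu_grid, strictly = TRUE)) {
    stop("`mu_grid` must be strictly ascending")
  }
  s <- (mu_grid - mu_grid[1]) / (mu_grid[length(mu_grid)] - mu_grid[1])
  peak_s <- s[length(s) - 1]
  out <- t(vapply(1:4, function(k) {
    template_value(as.character(k), s, amplitude_log2, peak_s)
  }, numeric(length(mu_grid))))
  dimnames(out) <- list(cluster = as.character(1:4),
                        mu = format(mu_grid, trim = TRUE))
  out
}

# run expr with a private, restored RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# largest-remainder apportionment of `size` items to proportions `p`
apportion <- function(size, p) {
  base <- floor(p * size)
  rem <- size - sum(base)
  if (rem > 0) {
    frac <- p * size - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1L
  }
  as.integer(base)
}

# enumerate the sampling design of a config, minus drops
enumerate_design <- function(config) {
  d <- expand.grid(mu = config$mu_grid,
                   replicate = seq_len(config$replicates_per_point),
                   condition = config$conditions,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("condition", "replicate", "mu")]
  if (nrow(config$dropped_samples) > 0) {
    key <- function(x) paste(x$condition, x$replicate, round(x$mu, 6))
    d <- d[!(key(d) %in% key(config$dropped_samples)), , drop = FALSE]
  }
  d <- d[order(match(d$condition, config$conditions), d$replicate, d$mu), ,
         drop = FALSE]
  rownames(d) <- NULL
  cond_letter <- toupper(substr(d$condition, 1, 1))
  d$sample_id <- paste0(cond_letter, d$replicate, "-",
                        format(d$mu, trim = TRUE, drop0trailing = TRUE))
  # nominal sampling time: condition-specific lag + ramp position
  lags <- stats::setNames(
    rep(c(4, 10, 1), length.out = length(config$conditions)),
    config$conditions)
  mu_max <- max(config$mu_grid)
  d$time_h <- lags[d$condition] + 6 * d$mu / mu_max
  d
}

#' Simulate a growth-rate-course count matrix with planted ground truth
#'
#' Draws negative-binomial counts (gamma-Poisson; variance = m + phi m^2)
#' for every sample of the configured design. A planted modulon follows one
#' of four log2 profile shapes (see [make_profile_templates()]) relative to
#' the reference growth rate, identically in every condition;
#' condition-private DEGs follow a random shape in a random subset of one or
#' two conditions and are flat elsewhere; all remaining genes are flat in
#' mu. Per-sample library sizes are drawn log-uniformly within the
#' configured range. Output is bit-reproducible for a fixed seed.
#'
#' @param config A [simulation_config()].
#' @return List with components `counts` (a [count_matrix()]), `meta`
#'   (sample metadata data frame: sample_id, condition, replicate, mu,
#'   time_h), and `truth` (ground truth: `modulon_genes`, `cluster_of_gene`,
#'   `private_deg_genes`, `enriched_regulators` (filled by
#'   [simulate_network()]), `mean_profile` data frame of expected log2
#'   expression relative to the reference rate).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    genes <- sprintf("cg%04d", seq_len(config$n_genes))
    design <- enumerate_design(config)
    templates <- if (config$modulon_size > 0 ||
                       config$condition_private_deg_count > 0) {
      make_profile_templates(config$mu_grid, config$amplitude_log2)
    } else NULL

    modulon <- sort(sample(genes, config$modulon_size))
    cluster_sizes <- apportion(config$modulon_size,
                               config$cluster_proportions)
    cluster_of <- stats::setNames(
      sample(rep.int(1:4, cluster_sizes)), modulon)
    remaining <- setdiff(genes, modulon)
    private <- sort(sample(remaining, config$condition_private_deg_count))
    n_cond <- length(config$conditions)
    private_spec <- lapply(private, function(g) {
      k <- sample(1:2, 1)
      list(conditions = sample(config$conditions, min(k, n_cond)),
           cluster = sample(1:4, 1),
           sign = sample(c(1, -1), 1))
    })
    names(private_spec) <- private
    private_by_cond <- lapply(config$conditions, function(cc) {
      names(private_spec)[vapply(private_spec,
                                 function(s) cc %in% s$conditions,
                                 logical(1))]
    })
    names(private_by_cond) <- config$conditions

    # log2 fold change (vs reference mu) for every gene at (condition, mu)
    l2fc_at <- function(condition, mu) {
      out <- numeric(config$n_genes)
      names(out) <- genes
      col <- which(abs(config$mu_grid - mu) < 1e-9)
      if (config$modulon_size > 0) {
        out[modulon] <- templates[cluster_of[modulon], col]
      }
      for (g in private_by_cond[[condition]]) {
        sp <- private_spec[[g]]
        out[g] <- sp$sign * templates[sp$cluster, col]
      }
      out
    }

    base_q <- stats::setNames(exp(stats::rnorm(config$n_genes, 0, 1.5)),
                              genes)
    lib <- exp(stats::runif(nrow(design),
                            log(config$library_size_range[1]),
                            log(config$library_size_range[2])))
    phi <- config$nb_dispersion
    counts <- matrix(0L, nrow = config$n_genes, ncol = nrow(design),
                     dimnames = list(genes, design$sample_id))
    for (j in seq_len(nrow(design))) {
      w <- base_q * 2^l2fc_at(design$condition[j], design$mu[j])
      m <- lib[j] * w / sum(w)
      counts[, j] <- if (phi > 0) {
        stats::rnbinom(config$n_genes, mu = m, size = 1 / phi)
      } else {
        stats::rpois(config$n_genes, m)
      }
    }

    mean_profile <- NULL
    special <- c(modulon, private)
    if (length(special) > 0) {
      grid_list <- lapply(config$conditions, function(cc) {
        mus <- sort(unique(design$mu[design$condition == cc]))
        do.call(rbind, lapply(mus, function(m) {
          l2 <- l2fc_at(cc, m)[special]
          data.frame(gene = special, condition = cc, mu = m,
                     log2_rel = unname(l2), stringsAsFactors = FALSE)
        }))
      })
      mean_profile <- do.call(rbind, grid_list)
      rownames(mean_profile) <- NULL
    }

    truth <- structure(
      list(modulon_genes = modulon,
           cluster_of_gene = cluster_of,
           private_deg_genes = private_by_cond,
           enriched_regulators = character(0),
           mean_profile = mean_profile),
      class = "ground_truth")

    list(counts = count_matrix(counts),
         meta = design[, c("sample_id", "condition", "replicate", "mu",
                           "time_h")],
         truth = truth)
  })
}

#' Simulate a regulatory network with planted enriched regulons
#'
#' Builds a regulator -> target edge list. The first
#' `planted_enriched_regulons` regulators draw a fraction
#' `planted_modulon_fraction` (>= 1/2) of their targets from the planted
#' modulon; all other regulons sample targets uniformly from the gene pool.
#' Planted regulon sizes are drawn from the upper half of
#' `regulon_size_range`: a very small regulon (e.g. 5 targets, 3 in the
#' modulon) is not statistically enriched at usual FDR levels even when the
#' modulon is known exactly, so planting it would violate the intent that
#' planted regulons be recoverably enriched; background regulons use the
#' full size range. No duplicate edges are produced (targets are sampled
#' without replacement within a regulon).
#'
#' @param config A [simulation_config()].
#' @param truth Ground truth from [simulate_counts()].
#' @return Data frame with columns `regulator`, `target`; the planted
#'   regulator ids are in `attr(, "enriched_regulators")`.
#' @export
simulate_network <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "ground_truth"))
  with_seed(config$seed + 1L, {
    genes <- sprintf("cg%04d", seq_len(config$n_genes))
    modulon <- truth$modulon_genes
    non_modulon <- setdiff(genes, modulon)
    edges <- vector("list", config$n_regulons)
    regs <- sprintf("Reg%02d", seq_len(config$n_regulons))
    size_lo <- config$regulon_size_range[1]
    size_hi <- config$regulon_size_range[2]
    planted_lo <- max(size_lo, ceiling((size_lo + size_hi) / 2))
    for (i in seq_len(config$n_regulons)) {
      planted <- i <= config$planted_enriched_regulons &&
        length(modulon) > 0
      size <- if (planted) {
        sample(seq(planted_lo, size_hi), 1)
      } else {
        sample(seq(size_lo, size_hi), 1)
      }
      targets <- if (planted) {
        k_in <- max(ceiling(size / 2),
                    round(config$planted_modulon_fraction * size))
        k_in <- min(k_in, length(modulon))
        c(sample(modulon, k_in),
          sample(non_modulon, size - k_in))
      } else {
        sample(genes, size)
      }
      edges[[i]] <- data.frame(regulator = regs[i], target = targets,
                               stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, edges)
    rownames(out) <- NULL
    attr(out, "enriched_regulators") <-
      regs[seq_len(config$planted_enriched_regulons)]
    out
  })
}

#' Growth-rate ramp used by the curve simulator
#'
#' Zero during the lag phase, then a linear increase to `mu_max` over
#' `ramp_h` hours, then constant.
#'
#' @param t Time(s), h.
#' @param lag_h Lag duration, h.
#' @param mu_max Maximum growth rate, 1/h.
#' @param ramp_h Acceleration duration, h.
#' @return Growth rate(s), 1/h.
#' @export
ramp_mu <- function(t, lag_h, mu_max, ramp_h) {
  pmin(pmax((t - lag_h) / ramp_h, 0), 1) * mu_max
}

#' Simulate a growth-rate-transition CDW curve
#'
#' Total cell dry weight is the sum of a constant dead-biomass fraction
#' (set by the inoculum viability) and a viable fraction growing with the
#' smooth rate ramp [ramp_mu()]; optional additive Gaussian measurement
#' noise. The generating rate function is recoverable from the noiseless
#' curve via [mu_differential()].
#'
#' @param viability_percent Inoculum viability in (0, 100].
#' @param lag_h Lag duration, h.
#' @param mu_max Maximum growth rate, 1/h (> 0).
#' @param noise_sd Measurement noise SD, g/L.
#' @param times Sampling times, h (ascending, starting at 0).
#' @param ramp_h Acceleration duration, h.
#' @param cdw0 Total CDW at inoculation, g/L.
#' @param condition Condition label.
#' @return A [growth_series()].
#' @export
simulate_growth_curve <- function(viability_percent, lag_h = 2,
                                  mu_max = 0.4, noise_sd = 0,
                                  times = seq(0, lag_h + ramp_h + 2,
                                              by = 0.25),
                                  ramp_h = 6, cdw0 = 1.2,
                                  condition = NA_character_) {
  if (viability_percent <= 0 || viability_percent > 100) {
    stop("`viability_percent` must be in (0, 100]")
  }
  if (mu_max <= 0) stop("`mu_max` must be positive")
  v <- viability_percent / 100
  dead <- cdw0 * (1 - v)
  viable0 <- cdw0 * v
  # analytic integral of ramp_mu from 0 to t
  int_mu <- function(t) {
    u <- pmin(pmax(t - lag_h, 0), ramp_h)
    mu_max * (u^2 / (2 * ramp_h) + pmax(t - lag_h - ramp_h, 0))
  }
  cdw <- dead + viable0 * exp(int_mu(times))
  if (noise_sd > 0) {
    cdw <- pmax(cdw + stats::rnorm(length(times), 0, noise_sd), 1e-6)
  }
  growth_series(times, cdw, viability_percent, condition)
}

#' Write/read ground truth as JSON
#'
#' @param truth A `ground_truth` object.
#' @param path File path.
#' @return `write_ground_truth_json` returns `path` invisibly;
#'   `read_ground_truth_json` returns a `ground_truth` object.
#' @export
write_ground_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  x <- list(
    modulon_genes = truth$modulon_genes,
    cluster_of_gene = as.list(truth$cluster_of_gene),
    private_deg_genes = truth$private_deg_genes,
    enriched_regulators = truth$enriched_regulators,
    mean_profile = truth$mean_profile
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "list")
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(modulon_genes = as.character(x$modulon_genes),
         cluster_of_gene = unlist(x$cluster_of_gene),
         private_deg_genes = lapply(x$private_deg_genes, as.character),
         enriched_regulators = as.character(x$enriched_regulators),
         mean_profile = as.data.frame(x$mean_profile)),
    class = "ground_truth")
}
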