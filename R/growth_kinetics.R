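#' Construct a growth series
#'
#' A `growth_series` holds timestamped cell dry weight (CDW) measurements for
#' one culture together with the percent viability of the inoculum, measured
#' as colony-forming units relative to a mid-exponential reference culture.
#' The viability is used to split total biomass into a viable, growing
#' fraction and a dead, inert fraction carried over from the pre-culture.
#'
#' @param time Numeric vector of sampling times in hours, strictly
#'   increasing; the first entry is the inoculation point.
#' @param cdw Numeric vector of cell dry weight in g/L, positive, same
#'   length as `time`.
#' @param viability_percent Percent viability at inoculation, in (0, 100].
#' @param condition Optional condition label (e.g. `"phosphate"`).
#' @return An object of class `growth_series`.
#' @export
growth_series <- function(time, cdw, viability_percent = 100,
                          condition = NA_character_) {
  if (length(time) != length(cdw)) {
    stop("`time` and `cdw` must have the same length")
  }
  if (any(!is.finite(time)) || any(!is.finite(cdw))) {
    stop("`time` and `cdw` must be finite")
  }
  if (length(time) >= 2 && any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing")
  }
  if (any(cdw <= 0)) stop("`cdw` must be positive everywhere")
  if (!is.numeric(viability_percent) || length(viability_percent) != 1 ||
      viability_percent <= 0 || viability_percent > 100) {
    stop("`viability_percent` must be a single value in (0, 100]")
  }
  structure(
    list(time = as.numeric(time), cdw = as.numeric(cdw),
         viability_percent = as.numeric(viability_percent),
         condition = condition),
    class = "growth_series"
  )
}

#' @export
print.growth_series <- function(x, ...) {
  cat(sprintf("growth_series: %d points over %.2f-%.2f h, viability %.1f%%",
              length(x$time), min(x$time), max(x$time),
              x$viability_percent))
  if (!is.na(x$condition)) cat(sprintf(" (%s)", x$condition))
  cat("\n")
  invisible(x)
}

#' Percent viability from colony-forming unit counts
#'
#' One hundred percent viability is defined by the colony count of a
#' mid-exponential reference sample; the viability of any other sample is
#' its CFU density relative to that reference. Values above 100 are
#' possible (the sample outgrew the reference) and are returned as-is with
#' a warning rather than clipped.
#'
#' @param cfu_per_ml_sample CFU per mL of the sample.
#' @param cfu_per_ml_reference CFU per mL of the mid-exponential reference;
#'   must be positive.
#' @return Percent viability (numeric).
#' @export
viability_percent <- function(cfu_per_ml_sample, cfu_per_ml_reference) {
  if (any(cfu_per_ml_reference <= 0)) {
    stop("reference CFU count must be positive")
  }
  if (any(cfu_per_ml_sample < 0)) stop("sample CFU count must be non-negative")
  v <- 100 * cfu_per_ml_sample / cfu_per_ml_reference
  if (any(v > 100)) {
    warning("viability exceeds 100%; returned unclipped")
  }
  v
}

#' Viability-adjusted differential growth rate
#'
#' Computes the instantaneous specific growth rate between consecutive CDW
#' measurements, considering only the viable cell population. The inoculum
#' contains a dead biomass fraction `cdw[1] * (1 - viability/100)` that
#' contributes to every CDW measurement without growing; it is subtracted
#' from each measurement before taking log ratios:
#' \deqn{\mu_{diff,t} = \ln\!\frac{c_{x,t} - c_{dead}}{c_{x,t-1} - c_{dead}}
#'   \, / \, (t - t_{-1})}
#' With 100% viability the dead offset is zero and the result is the
#' ordinary log-ratio specific growth rate. Rates may be negative during a
#' lag phase (biomass decline); they are not clipped.
#'
#' An alternative `as_printed` mode subtracts the viable inoculum biomass
#' `cdw[1] * viability/100` instead; it is provided for comparison with a
#' literal reading of the published formula but contradicts the stated
#' intent of correcting for nonviable biomass (at 100% viability it would
#' subtract the whole inoculum), so the dead-biomass subtraction is the
#' default.
#'
#' @param series A [growth_series()].
#' @param as_printed Logical; subtract the viable (rather than dead)
#'   inoculum biomass. Default `FALSE`.
#' @return An object of class `mu_series`: a list with `interval_midpoint_time`
#'   (h), `mu_diff` (1/h, one per consecutive CDW pair), and `time_range`.
#' @export
mu_differential <- function(series, as_printed = FALSE) {
  stopifnot(inherits(series, "growth_series"))
  if (length(series$time) < 2) stop("need at least 2 time points")
  v <- series$viability_percent / 100
  offset <- if (as_printed) series$cdw[1] * v else series$cdw[1] * (1 - v)
  viable <- series$cdw - offset
  if (any(viable <= 0)) {
    bad <- series$time[which(viable <= 0)[1]]
    stop(sprintf(
      "non-positive viable biomass at t = %g h; check viability/offsets", bad))
  }
  dt <- diff(series$time)
  if (any(dt == 0)) stop("zero time step between measurements")
  mu <- diff(log(viable)) / dt
  structure(
    list(
      interval_midpoint_time = (series$time[-1] +
                                  series$time[-length(series$time)]) / 2,
      mu_diff = mu,
      time_range = range(series$time),
      condition = series$condition
    ),
    class = "mu_series"
  )
}

#' @export
print.mu_series <- function(x, ...) {
  cat(sprintf("mu_series: %d intervals, mu_diff in [%.3f, %.3f] 1/h\n",
              length(x$mu_diff), min(x$mu_diff), max(x$mu_diff)))
  invisible(x)
}

#' Interpolated growth rate at arbitrary times
#'
#' The differential rate of each interval is attached to the interval
#' midpoint and a two-point line is fitted between each pair of neighbouring
#' midpoints, i.e. the growth rate is assumed to increase linearly between
#' measurement intervals. Outside the first/last midpoint (but within the
#' observed time range) the nearest interval's rate is used; evaluation
#' outside the observed time range is an error.
#'
#' @param series A `mu_series` from [mu_differential()].
#' @param t Numeric vector of times (h) at which to evaluate the rate.
#' @return Numeric vector of growth rates (1/h).
#' @export
mu_at <- function(series, t) {
  stopifnot(inherits(series, "mu_series"))
  if (any(t < series$time_range[1] - 1e-12 |
            t > series$time_range[2] + 1e-12)) {
    stop("time outside the observed range; extrapolation not supported")
  }
  mids <- series$interval_midpoint_time
  if (length(mids) == 1) return(rep(series$mu_diff, length(t)))
  stats::approx(mids, series$mu_diff, xout = t, rule = 2)$y
}

#' Select samples closest to target growth rates
#'
#' For each target growth rate, picks the candidate sample whose
#' interpolated differential growth rate is closest to the target; ties are
#' broken by earliest sampling time. A candidate may serve several targets;
#' such selections are flagged in the `reused` column.
#'
#' @param candidates Data frame with columns `sample_id` and `time` (h);
#'   times must lie within the `mu_series` time range.
#' @param series A `mu_series`.
#' @param targets Numeric vector of target growth rates (1/h).
#' @return Data frame with columns `target_mu`, `sample_id`, `time`,
#'   `achieved_mu`, `reused`.
#' @export
select_samples <- function(candidates, series, targets) {
  stopifnot(inherits(series, "mu_series"))
  if (!is.data.frame(candidates) ||
      !all(c("sample_id", "time") %in% names(candidates))) {
    stop("`candidates` must be a data frame with sample_id and time")
  }
  if (nrow(candidates) == 0) stop("empty candidate list")
  mu_cand <- mu_at(series, candidates$time)
  out <- lapply(targets, function(tg) {
    err <- abs(mu_cand - tg)
    best <- which(err == min(err))
    if (length(best) > 1) best <- best[which.min(candidates$time[best])]
    data.frame(target_mu = tg,
               sample_id = candidates$sample_id[best],
               time = candidates$time[best],
               achieved_mu = mu_cand[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$reused <- duplicated(out$sample_id) |
    duplicated(out$sample_id, fromLast = TRUE)
  if (any(out$reused)) {
    warning("one sample serves multiple targets; see `reused` column")
  }
  out
}

#' Time to deplete a substrate at constant biomass-specific uptake
#'
#' Zero-order depletion estimate: `concentration / (uptake_rate * biomass)`.
#' Used e.g. to estimate how quickly a medium supplement such as
#' protocatechuic acid is exhausted after inoculation.
#'
#' @param concentration_mmol_l Substrate concentration in mmol/L.
#' @param uptake_mmol_gcdw_h Biomass-specific uptake rate in mmol/gCDW/h.
#' @param biomass_gcdw_l Biomass concentration in gCDW/L.
#' @return Depletion time in hours.
#' @export
substrate_depletion_time <- function(concentration_mmol_l,
                                     uptake_mmol_gcdw_h,
                                     biomass_gcdw_l) {
  if (uptake_mmol_gcdw_h <= 0 || biomass_gcdw_l <= 0) {
    stop("uptake rate and biomass must be positive")
  }
  concentration_mmol_l / (uptake_mmol_gcdw_h * biomass_gcdw_l)
}

#' Read/write growth-curve tables
#'
#' Plain TSV with columns `time_h` and `cdw_gL`.
#'
#' @param path File path.
#' @param series A [growth_series()] (for writing).
#' @param viability_percent,condition Passed to [growth_series()] when
#'   reading.
#' @return `read_growth_curve_tsv` returns a [growth_series()];
#'   `write_growth_curve_tsv` returns `path` invisibly.
#' @export
read_growth_curve_tsv <- function(path, viability_percent = 100,
                                  condition = NA_character_) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "cdw_gL") %in% names(d))) {
    stop("growth curve TSV needs columns time_h and cdw_gL")
  }
  growth_series(d$time_h, d$cdw_gL, viability_percent, condition)
}

#' @rdname read_growth_curve_tsv
#' @export
write_growth_curve_tsv <- function(series, path) {
  stopifnot(inherits(series, "growth_series"))
  utils::write.table(
    data.frame(time_h = series$time, cdw_gL = series$cdw),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a differential growth-rate table
#'
#' @param series A `mu_series`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_mu_tsv <- function(series, path) {
  stopifnot(inherits(series, "mu_series"))
  utils::write.table(
    data.frame(time_h = series$interval_midpoint_time,
               mu_diff_per_h = series$mu_diff),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
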