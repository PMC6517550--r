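test_that("viability is the CFU ratio relative to the reference", {
  expect_equal(viability_percent(150, 150), 100)
  expect_equal(viability_percent(90, 150), 60)
  expect_equal(viability_percent(0, 150), 0)
  expect_warning(v <- viability_percent(180, 150), "100")
  expect_equal(v, 120)  # unclipped
  expect_error(viability_percent(10, 0), "positive")
})

test_that("growth_series validates its inputs", {
  expect_error(growth_series(c(0, 1, 1), c(1, 2, 3)), "increasing")
  expect_error(growth_series(c(0, 1), c(1, -1)), "positive")
  expect_error(growth_series(c(0, 1), c(1, 2), viability_percent = 0),
               "0, 100")
  expect_s3_class(growth_series(0:3, c(1, 1.2, 1.5, 2)), "growth_series")
})

test_that("viability-adjusted rate subtracts dead biomass and divides by dt", {
  # full viability: ordinary log-ratio growth rate, machine precision
  gs <- growth_series(c(0, 1), c(1, exp(1)), viability_percent = 100)
  expect_equal(mu_differential(gs)$mu_diff, 1.0, tolerance = 1e-14)

  # constant biomass: zero rate everywhere
  gs <- growth_series(0:4, rep(2.5, 5))
  expect_equal(mu_differential(gs)$mu_diff, rep(0, 4))

  # hand-computed case: v0 = 60%, c0 = 1.2 -> dead biomass 0.48;
  # mu = ln((2.4 - 0.48)/(2.0 - 0.48)) / 1 h
  gs <- growth_series(c(0, 5, 6), c(1.2, 2.0, 2.4),
                      viability_percent = 60)
  ms <- mu_differential(gs)
  expect_equal(ms$mu_diff[2], log(1.92 / 1.52), tolerance = 1e-12)

  # as-printed mode subtracts the viable inoculum instead
  ms2 <- mu_differential(gs, as_printed = TRUE)
  expect_equal(ms2$mu_diff[2], log((2.4 - 0.72) / (2.0 - 0.72)),
               tolerance = 1e-12)

  # rates may go negative during decline, never clipped
  gs <- growth_series(c(0, 1), c(2, 1.5))
  expect_lt(mu_differential(gs)$mu_diff, 0)
})

test_that("scaling all CDW values leaves the rate unchanged", {
  set.seed(1)
  cdw <- cumprod(c(1.5, exp(runif(6, 0, 0.3))))
  gs1 <- growth_series(0:6, cdw, viability_percent = 80)
  gs2 <- growth_series(0:6, 10 * cdw, viability_percent = 80)
  expect_equal(mu_differential(gs1)$mu_diff, mu_differential(gs2)$mu_diff,
               tolerance = 1e-12)
})

test_that("rate computation rejects degenerate series", {
  gs <- growth_series(c(0, 1), c(1, 2), viability_percent = 100)
  gs$cdw <- c(1, 2); gs$time <- c(0, 0)  # forced zero step
  expect_error(mu_differential(gs), "zero time step")
  # dead-biomass offset exceeding a later measurement
  gs2 <- growth_series(c(0, 1, 2), c(2, 0.5, 3), viability_percent = 50)
  expect_error(mu_differential(gs2), "non-positive viable biomass")
})

test_that("rate interpolation is exact at midpoints and linear between", {
  gs <- growth_series(c(0, 1, 2, 3), c(1, 1.1, 1.4, 2.0))
  ms <- mu_differential(gs)
  expect_equal(mu_at(ms, ms$interval_midpoint_time), ms$mu_diff)
  # halfway between midpoints with rates a and b -> (a + b) / 2
  mid12 <- mean(ms$interval_midpoint_time[1:2])
  expect_equal(mu_at(ms, mid12), mean(ms$mu_diff[1:2]), tolerance = 1e-12)
  # brute-force two-point line at random times
  set.seed(42)
  for (t in runif(20, ms$interval_midpoint_time[1],
                  ms$interval_midpoint_time[3])) {
    i <- findInterval(t, ms$interval_midpoint_time,
                      rightmost.closed = TRUE)
    i <- min(max(i, 1), 2)
    t0 <- ms$interval_midpoint_time[i]; t1 <- ms$interval_midpoint_time[i + 1]
    line <- ms$mu_diff[i] + (ms$mu_diff[i + 1] - ms$mu_diff[i]) *
      (t - t0) / (t1 - t0)
    expect_equal(mu_at(ms, t), line, tolerance = 1e-12)
  }
  expect_error(mu_at(ms, 5), "outside")
})

test_that("sample selection minimizes |mu - target| with earliest-time ties", {
  gs <- simulate_growth_curve(100, lag_h = 2, mu_max = 0.4, ramp_h = 6,
                              times = seq(0, 10, 0.5))
  ms <- mu_differential(gs)
  set.seed(3)
  cand <- data.frame(
    sample_id = sprintf("s%03d", 1:100),
    time = runif(100, min(ms$interval_midpoint_time),
                 max(ms$interval_midpoint_time)))
  targets <- c(0, 0.1, 0.2, 0.3, 0.4)
  sel <- suppressWarnings(select_samples(cand, ms, targets))
  expect_equal(nrow(sel), 5)
  mu_cand <- mu_at(ms, cand$time)
  for (i in seq_along(targets)) {
    err <- abs(mu_cand - targets[i])
    best <- which(err == min(err))
    if (length(best) > 1) best <- best[which.min(cand$time[best])]
    expect_equal(sel$sample_id[i], cand$sample_id[best])
  }
  # one candidate reused for several targets gets flagged
  one <- data.frame(sample_id = "only", time = ms$interval_midpoint_time[5])
  expect_warning(sel1 <- select_samples(one, ms, c(0.1, 0.2)), "multiple")
  expect_true(all(sel1$reused))
  expect_error(select_samples(cand[0, ], ms, 0.1), "empty")
})

test_that("noiseless simulated curves round-trip the generating rate", {
  for (v in c(100, 88, 60)) {
    gs <- simulate_growth_curve(v, lag_h = 2, mu_max = 0.4, ramp_h = 6,
                                noise_sd = 0, times = seq(0, 10, 0.25))
    ms <- mu_differential(gs)
    expect_equal(ms$mu_diff,
                 ramp_mu(ms$interval_midpoint_time, 2, 0.4, 6),
                 tolerance = 1e-6)
  }
  # v = 100 and no noise: curve is exactly the exponential of the ramp
  gs <- simulate_growth_curve(100, lag_h = 1, mu_max = 0.3, ramp_h = 4,
                              noise_sd = 0, times = seq(0, 7, 0.5),
                              cdw0 = 1.2)
  int_mu <- function(t) {
    u <- pmin(pmax(t - 1, 0), 4)
    0.3 * (u^2 / 8 + pmax(t - 5, 0))
  }
  expect_equal(gs$cdw, 1.2 * exp(int_mu(gs$time)), tolerance = 1e-12)
  # v = 60: viable inoculum biomass is 60% of initial CDW
  gs60 <- simulate_growth_curve(60, lag_h = 2, mu_max = 0.4,
                                noise_sd = 0, cdw0 = 1.0)
  expect_equal(gs60$cdw[1], 1.0)                    # total unchanged
  expect_equal(gs60$cdw[1] - 0.4, 0.6 * gs60$cdw[1])  # viable fraction
})

test_that("substrate depletion time follows zero-order kinetics", {
  expect_equal(substrate_depletion_time(0.2, 2.04, 1.2),
               0.2 / (2.04 * 1.2), tolerance = 1e-12)
  expect_error(substrate_depletion_time(0.2, 0, 1.2), "positive")
})

test_that("growth curve and mu tables round-trip through TSV", {
  gs <- simulate_growth_curve(88, lag_h = 1, times = seq(0, 9, 0.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_growth_curve_tsv(gs, path)
  gs2 <- read_growth_curve_tsv(path, viability_percent = 88)
  expect_equal(gs2$time, gs$time)
  expect_equal(gs2$cdw, gs$cdw, tolerance = 1e-6)
})
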