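# small synthetic dataset builder for hand-crafted spike times
manual_dataset <- function(spikes, n_trials, pre_s = 5, light_s = 5,
                           post_s = 5, lpd = 1) {
  events <- do.call(rbind, lapply(seq_along(spikes), function(u) {
    do.call(rbind, lapply(seq_along(spikes[[u]]), function(tr) {
      tt <- spikes[[u]][[tr]]
      if (!length(tt)) return(NULL)
      data.frame(unit = u, trial = tr, lpd = lpd, time = sort(tt))
    }))
  }))
  if (is.null(events)) events <- data.frame(unit = integer(), trial = integer(),
                                            lpd = numeric(), time = numeric())
  structure(list(events = events,
                 unit_index = split(seq_len(nrow(events)), events$unit),
                 protocol = list(pre_s = pre_s, light_s = light_s,
                                 post_s = post_s, n_trials = n_trials,
                                 lpd_levels = lpd)),
            class = "spike_dataset")
}

test_that("suppression classifier flags only directional significant changes", {
  # 10 spikes pre, none during light, every trial: maximal suppression
  tr10 <- lapply(1:10, function(i) seq(-4.9, -0.1, length.out = 10))
  ds <- manual_dataset(list(tr10), n_trials = 10)
  r <- classify_suppressed(ds, 1)
  expect_true(r$suppressed)
  expect_equal(r$mean_light, 0)
  # identical pre/light counts: p = 1, not flagged
  sym <- lapply(1:10, function(i) c(seq(-4.5, -0.5, 1), seq(0.5, 4.5, 1)))
  ds2 <- manual_dataset(list(sym), n_trials = 10)
  r2 <- classify_suppressed(ds2, 1)
  expect_false(r2$suppressed)
  expect_equal(r2$p, 1)
  # significant increase must NOT be flagged as suppression
  up <- lapply(1:10, function(i) c(-2, seq(0.1, 4.9, length.out = 12 + i %% 2)))
  ds3 <- manual_dataset(list(up), n_trials = 10)
  r3 <- classify_suppressed(ds3, 1)
  expect_false(r3$suppressed)
  expect_lt(r3$p, 0.05)
})

test_that("relative firing rate matches pooled definition and generator truth", {
  tr <- lapply(1:10, function(i) c(seq(-4.75, -0.25, 0.5), 2.5))  # 10 pre, 1 light
  ds <- manual_dataset(list(tr), n_trials = 10)
  expect_equal(relative_fr(ds, 1), 0.1)
  # zero pre-light rate: undefined
  dsz <- manual_dataset(list(lapply(1:10, function(i) 2.5)), n_trials = 10)
  expect_true(is.na(relative_fr(dsz, 1)))
  expect_true(attr(relative_fr(dsz, 1), "undefined"))
  # generator round trip at s = 0.8 over 200 units
  cfg <- sim_config(seed = 1, n_units = 200, baseline_rate_hz = 5,
                    suppression_fraction = 0.8, n_trials = 10, post_s = 0.5)
  dsg <- gen_spike_dataset(cfg)
  rf <- vapply(1:200, function(u) relative_fr(dsg, u), numeric(1))
  rf <- rf[!is.na(rf)]
  expect_lt(abs(mean(rf) - 0.2), 3 * sd(rf) / sqrt(length(rf)))
})

test_that("relative-rate PSTH is flat at 1 for null units and tracks rebound", {
  cfg0 <- sim_config(seed = 4, n_units = 30, baseline_rate_hz = 20,
                     suppression_fraction = 0, n_trials = 40, post_s = 2)
  ds0 <- gen_spike_dataset(cfg0)
  p0 <- psth_relative(ds0, lpd = 1, bin_s = 0.5)
  expect_true(all(abs(p0$rel_rate - 1) < 0.15))
  expect_equal(mean(p0$rel_rate), 1, tolerance = 0.02)
  # complete suppression: light bins at 0
  cfg1 <- sim_config(seed = 5, n_units = 10, baseline_rate_hz = 20,
                     suppression_fraction = 1, n_trials = 10, post_s = 1)
  p1 <- psth_relative(gen_spike_dataset(cfg1), bin_s = 0.5)
  light_bins <- p1$bin_start >= 0 & p1$bin_start < 5
  expect_true(all(p1$rel_rate[light_bins] == 0))
  # rebound: post-offset bins exceed 1 and match the analytic transient
  g <- 1.5; tau <- 0.5
  cfgr <- sim_config(seed = 6, n_units = 30, baseline_rate_hz = 20,
                     suppression_fraction = 1, rebound_gain = g,
                     rebound_tau_s = tau, n_trials = 30, post_s = 2)
  pr <- psth_relative(gen_spike_dataset(cfgr), bin_s = 0.25)
  first_post <- which(pr$bin_start >= 5)[1]
  expect_gt(pr$rel_rate[first_post], 1.2)
  # analytic bin average of 1 + g exp(-(t - 5)/tau) over the first post bin
  expected <- 1 + g * tau / 0.25 * (1 - exp(-0.25 / tau))
  expect_equal(pr$rel_rate[first_post], expected, tolerance = 0.15)
})

test_that("antidromic classifier recovers deterministic and generated latencies", {
  w <- 0.020
  # one spike at +3 ms every trial, silent pre-window
  det <- manual_dataset(list(lapply(1:20, function(i) 0.003)),
                        n_trials = 20, pre_s = 1, light_s = 0.005, post_s = 1)
  r <- classify_antidromic(det, 1)
  expect_true(r$antidromic)
  expect_equal(r$mean_latency_ms, 3)
  expect_equal(r$n_responsive_trials, 20)
  # silent unit: not flagged, latency undefined
  sil <- manual_dataset(list(lapply(1:20, function(i) numeric(0))),
                        n_trials = 20, pre_s = 1, light_s = 0.005, post_s = 1)
  rs <- classify_antidromic(sil, 1)
  expect_false(rs$antidromic)
  expect_true(is.na(rs$mean_latency_ms))
  # generator: prob 0.9, latency 4 +/- 1 ms, 20 trials
  cfg <- sim_config(seed = 2, n_units = 8, baseline_rate_hz = 5,
                    suppression_fraction = 1, antidromic_prob = 0.9,
                    antidromic_latency_ms = 4, antidromic_jitter_ms = 1,
                    n_trials = 20, pre_s = 1, light_s = 0.005, post_s = 1)
  dsg <- gen_spike_dataset(cfg)
  res <- lapply(1:8, function(u) classify_antidromic(dsg, u))
  expect_true(all(vapply(res, `[[`, logical(1), "antidromic")))
  lats <- vapply(res, `[[`, numeric(1), "mean_latency_ms")
  expect_true(all(abs(lats - 4) < 0.5))
})

test_that("latency ordering is ascending with stable id tie-break", {
  tab <- data.frame(unit = c(3, 1, 2), mean_latency_ms = c(5, 2, 9))
  expect_equal(latency_order(tab)$mean_latency_ms, c(2, 5, 9))
  ties <- data.frame(unit = c(9, 2, 5), mean_latency_ms = c(4, 4, 4))
  expect_equal(latency_order(ties)$unit, c(2, 5, 9))
  set.seed(3)
  rnd <- data.frame(unit = 1:50, mean_latency_ms = runif(50))
  expect_equal(latency_order(rnd)$mean_latency_ms,
               sort(rnd$mean_latency_ms))
})

test_that("population summary reproduces construct comparisons and delegates to Fisher", {
  flags <- c(rep(TRUE, 21), rep(FALSE, 79), rep(TRUE, 51), rep(FALSE, 47))
  grp <- rep(c("GtACR2", "stGtACR2"), c(100, 98))
  s <- population_summary(flags, grp)
  expect_equal(s$fractions$fraction, c(0.21, 51 / 98))
  expect_equal(s$comparisons$statistic, 20.61, tolerance = 0.005)
  expect_match(s$comparisons$method, "chi-square")
  # identical groups: chi-square 0
  f0 <- c(rep(TRUE, 10), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 10))
  g0 <- rep(c("a", "b"), each = 20)
  expect_equal(population_summary(f0, g0)$comparisons$statistic, 0)
  # zero cell: falls through to Fisher's exact test
  fz <- c(rep(TRUE, 5), rep(FALSE, 15), rep(FALSE, 20))
  sz <- population_summary(fz, g0)
  expect_match(sz$comparisons$method, "Fisher")
})
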