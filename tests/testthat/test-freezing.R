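test_that("pixel_change counts exactly the flipped pixels", {
  frames <- array(0L, dim = c(64, 64, 4))
  frames[1:5, 1:4, 3] <- 255L          # 20 pixels flip between frames 2 and 3
  tr <- pixel_change(frames, "global", delta = 10)
  expect_equal(tr$values, c(0, 0, 20, 20))  # they flip back on frame 4
  expect_equal(tr$frame_pixels, 64 * 64)
  # sub-threshold intensity changes do not count
  frames2 <- array(0L, dim = c(64, 64, 2))
  frames2[, , 2] <- 5L
  expect_equal(pixel_change(frames2, "global", delta = 10)$values[2], 0)
  expect_error(pixel_change(array(0, c(64, 64, 1))), ">= 2")
})

test_that("ROI mode discards cord motion outside the animal region", {
  cfg <- sim_config(seed = 7, session_s = 6, fps = 25,
                    bout_schedule = list(c(2, 4)), cord_artifact = TRUE)
  st <- gen_frame_stack(cfg)
  truth <- attr(st, "truth")
  g <- pixel_change(st, "global")
  r <- pixel_change(st, "roi")
  # cord keeps moving during the bout: global sees it, the ROI does not
  expect_gt(mean(g$values[truth]), 0)
  expect_equal(sum(r$values[truth]), 0)
  expect_true(all(r$values <= g$values))
  # cord-only stack with a seeded animal ROI: ROI trace is exactly zero
  cfg2 <- sim_config(seed = 8, session_s = 2, fps = 25,
                     bout_schedule = list(c(0, 2)), cord_artifact = TRUE)
  st2 <- gen_frame_stack(cfg2)
  r2 <- pixel_change(st2, "roi", roi = list(rows = 20:60, cols = 1:64))
  g2 <- pixel_change(st2, "global")
  expect_equal(sum(r2$values), 0)
  expect_gt(sum(g2$values), 0)
})

test_that("Gaussian smoothing preserves constants and matches the dense oracle", {
  const <- pixel_trace(rep(1234, 60))
  expect_equal(smooth_trace(const)$values, rep(1234, 60), tolerance = 1e-12)
  # unit impulse reproduces the (renormalized) kernel, max at the impulse
  imp <- numeric(101); imp[51] <- 1
  sm <- smooth_trace(pixel_trace(imp), sigma_frames = 3)$values
  expect_equal(which.max(sm), 51)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  set.seed(9)
  for (sigma in c(1, 3, 5.5)) {
    x <- runif(80, 0, 1e4)
    mine <- smooth_trace(pixel_trace(x), sigma_frames = sigma)$values
    expect_equal(mine, oracle_gaussian_smooth(x, sigma), tolerance = 1e-9)
  }
  expect_warning(smooth_trace(pixel_trace(c(1, 2)), sigma_frames = 3),
                 "shorter")
})

test_that("freezing detection applies the run-length rule at the exact boundary", {
  mk <- function(n_low) pixel_trace(c(rep(1e4, 10), rep(0, n_low), rep(1e4, 10)))
  r38 <- detect_freezing(mk(38), threshold_px = 983, min_run_frames = 38)
  expect_equal(nrow(r38$bouts), 1)
  expect_equal(unname(r38$bouts[1, ]), c(10, 48))   # 0-based half-open
  expect_equal(sum(r38$frame_labels), 38)
  r37 <- detect_freezing(mk(37), threshold_px = 983, min_run_frames = 38)
  expect_equal(nrow(r37$bouts), 0)
  expect_false(any(r37$frame_labels))
  # ties at the threshold count as motion ("below" is strict)
  at_thr <- pixel_trace(rep(983, 50))
  expect_equal(sum(detect_freezing(at_thr, 983, 10)$frame_labels), 0)
  expect_error(detect_freezing(mk(38), 983, min_run_frames = 0), ">= 1")
})

test_that("freezing detection equals the brute-force window scan on random traces", {
  set.seed(10)
  for (i in 1:1000) {
    n <- sample(50:150, 1)
    thr <- runif(1, 0.3, 0.7)
    run <- sample(2:12, 1)
    vals <- runif(n)
    tr <- pixel_trace(vals, frame_pixels = round(thr / 0.005))
    mine <- detect_freezing(tr, threshold_px = thr, min_run_frames = run)
    expect_identical(mine$frame_labels,
                     oracle_freezing_labels(vals, thr, run))
  }
})

test_that("raising the threshold or lowering min_run never removes freezing", {
  set.seed(13)
  vals <- runif(300)
  tr <- pixel_trace(vals, frame_pixels = 100)
  for (i in 1:30) {
    t1 <- runif(1, 0.2, 0.5); t2 <- t1 + runif(1, 0, 0.4)
    r1 <- sum(suppressWarnings(detect_freezing(tr, t1, 5))$frame_labels)
    r2 <- sum(suppressWarnings(detect_freezing(tr, t2, 5))$frame_labels)
    expect_lte(r1, r2)
    m1 <- sample(2:10, 1); m2 <- m1 + sample(1:5, 1)
    f1 <- sum(suppressWarnings(detect_freezing(tr, 0.4, m1))$frame_labels)
    f2 <- sum(suppressWarnings(detect_freezing(tr, 0.4, m2))$frame_labels)
    expect_gte(f1, f2)
  }
})

test_that("canonical thresholds are mutually consistent", {
  expect_equal(min_run_from_duration(1.5, 25), 38L)
  expect_equal(min_run_from_duration(1.0, 25), 25L)
  expect_equal(min_run_from_duration(1.5, 30), 45L)
  # 983 px is 0.5% of the default 512 x 384 frame: no warning
  tr <- pixel_trace(rep(1e4, 100), frame_pixels = 196608)
  expect_equal(983, round(0.005 * tr$frame_pixels))
  expect_no_warning(detect_freezing(tr, threshold_px = 983))
  # a mismatched threshold warns
  expect_warning(detect_freezing(pixel_trace(rep(1e4, 100),
                                             frame_pixels = 4096),
                                 threshold_px = 983), "deviates")
})

test_that("per-window freezing percentages follow the protocol windows", {
  fps <- 25
  n <- 200 * fps
  labels <- rep(FALSE, n)
  # CS 1 at 40 s fully frozen; CS 2 at 120 s half frozen
  labels[(40 * fps + 1):(70 * fps)] <- TRUE
  labels[(120 * fps + 1):(135 * fps)] <- TRUE
  vals <- ifelse(labels, 0, 1e4)
  res <- detect_freezing(pixel_trace(vals), threshold_px = 983,
                         min_run_frames = 38)
  prot <- session_protocol(c(40, 120), cs_duration_s = 30, phase_n = 1)
  pct <- percent_freezing(res, prot)
  cs <- pct[pct$window == "cs", "percent"]
  pre <- pct[pct$window == "pre_cs", "percent"]
  expect_equal(cs[1], 100)
  expect_equal(cs[2], 50, tolerance = 0.2)   # within one frame quantum
  expect_equal(pre, c(0, 0))
  phases <- attr(pct, "phases")
  expect_equal(phases$percent[phases$window == "cs" & phases$phase == "early"],
               100)
  expect_error(percent_freezing(res, session_protocol(199)), "outside")
})

test_that("end-to-end: bouts in a generated session are recovered accurately", {
  cfg <- sim_config(seed = 7, session_s = 60,
                    bout_schedule = list(c(10, 20), c(35, 40)))
  tr <- gen_pixel_trace(cfg)
  res <- detect_freezing(smooth_trace(tr))
  acc <- mean(res$frame_labels == attr(tr, "truth"))
  expect_gte(acc, 0.99)
})
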