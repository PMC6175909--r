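#' Simulation configuration for synthetic silencing-experiment inputs
#'
#' Bundles and validates every parameter the generators use. Defaults follow
#' the in vivo silencing protocol the analyses are built around: 5 s light
#' pulses with 10 repetitions per light power density, 5 s pre/post windows,
#' 5 Hz baseline firing, behavioral video at 25 frames per second.
#'
#' @param seed global integer seed; all sub-streams derive from it.
#' @param n_units number of simulated units.
#' @param baseline_rate_hz baseline firing rate; a scalar (all units) or a
#'   vector of length `n_units`. Must be positive.
#' @param rate_sdlog when > 0 and `baseline_rate_hz` is scalar, per-unit rates
#'   are drawn log-normally around it with this sdlog (a convenience for
#'   heterogeneous populations; the defaults make no claim about real rate
#'   distributions).
#' @param suppression_fraction fraction of the baseline rate removed during
#'   the light window, in `[0, 1]`. May be a vector over `lpd_levels`.
#' @param responsive_fraction fraction of units that respond to light at all
#'   (expression heterogeneity); the remaining units keep their baseline rate
#'   during illumination. The first `round(responsive_fraction * n_units)`
#'   units are the responsive ones, recorded in the dataset's ground truth.
#' @param rebound_gain multiplicative transient rate gain after light offset
#'   (>= 0; 0 disables rebound).
#' @param rebound_tau_s decay constant of the rebound transient, s.
#' @param antidromic_prob per-trial probability of an inserted short-latency
#'   antidromic spike at light onset.
#' @param antidromic_latency_ms,antidromic_jitter_ms mean and Gaussian SD of
#'   the antidromic latency (truncated at 0).
#' @param n_trials trials per unit per light power density.
#' @param pre_s,light_s,post_s durations of the pre-light, light, and
#'   post-light epochs, s.
#' @param lpd_levels light power densities tested, mW mm^-2.
#' @param fps video frame rate, frames per s.
#' @param frame_shape c(height, width) of synthetic video frames, pixels.
#' @param session_s behavioral session duration, s.
#' @param bout_schedule list of c(start_s, end_s) freezing intervals.
#' @param motion_px,motion_sd_px mean and SD of the changed-pixel count per
#'   frame outside freezing bouts.
#' @param still_px,still_sd_px same inside freezing bouts (near zero).
#' @param cord_artifact logical; add a patch-cord motion component located
#'   outside the mouse region.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_units = 10L,
                       baseline_rate_hz = 5,
                       rate_sdlog = 0,
                       suppression_fraction = 0.8,
                       responsive_fraction = 1,
                       rebound_gain = 0,
                       rebound_tau_s = 0.5,
                       antidromic_prob = 0,
                       antidromic_latency_ms = 4,
                       antidromic_jitter_ms = 1,
                       n_trials = 10L,
                       pre_s = 5, light_s = 5, post_s = 5,
                       lpd_levels = 1,
                       fps = 25,
                       frame_shape = c(64L, 64L),
                       session_s = 60,
                       bout_schedule = list(),
                       motion_px = 5000, motion_sd_px = 1000,
                       still_px = 50, still_sd_px = 30,
                       cord_artifact = FALSE) {
  stop_if_not(length(seed) == 1 && is.finite(seed), "seed must be one integer")
  stop_if_not(all(baseline_rate_hz > 0), "baseline rate must be positive")
  stop_if_not(all(suppression_fraction >= 0 & suppression_fraction <= 1),
              "suppression_fraction must lie in [0, 1]")
  stop_if_not(responsive_fraction >= 0 && responsive_fraction <= 1,
              "responsive_fraction must lie in [0, 1]")
  stop_if_not(rebound_gain >= 0, "rebound_gain must be >= 0")
  stop_if_not(antidromic_prob >= 0 && antidromic_prob <= 1,
              "antidromic_prob must lie in [0, 1]")
  stop_if_not(all(c(pre_s, light_s, post_s, fps, session_s, rebound_tau_s) > 0),
              "durations and rates must be positive")
  stop_if_not(n_units >= 1 && n_trials >= 1, "need >= 1 unit and trial")
  if (length(bout_schedule)) {
    sb <- do.call(rbind, bout_schedule)
    stop_if_not(all(sb[, 1] < sb[, 2]), "bout start must precede bout end")
    stop_if_not(all(sb[, 1] >= 0 & sb[, 2] <= session_s),
                "bouts must lie within the session")
    o <- order(sb[, 1])
    if (nrow(sb) > 1 && any(sb[o[-nrow(sb)], 2] > sb[o[-1], 1]))
      stop("overlapping freezing bouts", call. = FALSE)
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

## time-varying rate profile of a simulated unit, relative to light onset at 0
rate_profile <- function(t, r0, s, g, tau_reb, light_s) {
  r <- rep(r0, length(t))
  in_light <- t >= 0 & t < light_s
  after <- t >= light_s
  r[in_light] <- r0 * (1 - s)
  r[after] <- r0 * (1 + g * exp(-(t[after] - light_s) / tau_reb))
  r
}

#' Generate a synthetic sorted spike dataset
#'
#' Draws per-unit, per-trial spike times from an inhomogeneous Poisson process
#' by thinning against the maximum-rate bound r0 * max(1, 1 + rebound_gain).
#' The rate is r0 (1 - s) during the light window, relaxes as
#' r0 (1 + g exp(-(t - t_off)/tau)) after offset, and is r0 elsewhere.
#' Antidromic spikes are inserted as extra events at onset + latency with the
#' configured per-trial probability (Gaussian jitter truncated at 0).
#' Refractoriness is deliberately ignored; no spiking model beyond the rate
#' profile is assumed.
#'
#' @param cfg a [sim_config()].
#' @return a `spike_dataset`: list with `events` (data.frame unit, trial, lpd,
#'   time — sorted within unit x trial), `protocol` (windows, trials, LPD
#'   levels), and `truth` (the generating parameters per unit).
#' @export
gen_spike_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg$seed, 1L))
  r0 <- if (length(cfg$baseline_rate_hz) == cfg$n_units) {
    cfg$baseline_rate_hz
  } else if (cfg$rate_sdlog > 0) {
    cfg$baseline_rate_hz * exp(rnorm(cfg$n_units, 0, cfg$rate_sdlog) -
                                 cfg$rate_sdlog^2 / 2)
  } else rep(cfg$baseline_rate_hz[1], cfg$n_units)
  s_levels <- rep_len(cfg$suppression_fraction, length(cfg$lpd_levels))
  responsive <- seq_len(cfg$n_units) <= round(cfg$responsive_fraction *
                                                cfg$n_units)
  t0 <- -cfg$pre_s
  t1 <- cfg$light_s + cfg$post_s
  span <- t1 - t0
  g <- cfg$rebound_gain
  out <- vector("list", cfg$n_units * length(cfg$lpd_levels) * cfg$n_trials)
  k <- 0L
  for (u in seq_len(cfg$n_units)) {
    rmax <- r0[u] * max(1, 1 + g)
    for (li in seq_along(cfg$lpd_levels)) {
      s <- if (responsive[u]) s_levels[li] else 0
      for (tr in seq_len(cfg$n_trials)) {
        set.seed(substream_seed(cfg$seed, u, li, tr))
        n_cand <- rpois(1, rmax * span)
        tt <- sort(runif(n_cand, t0, t1))
        keep <- runif(n_cand) < rate_profile(tt, r0[u], s, g,
                                             cfg$rebound_tau_s,
                                             cfg$light_s) / rmax
        spikes <- tt[keep]
        if (cfg$antidromic_prob > 0 && runif(1) < cfg$antidromic_prob) {
          lat <- max(0, rnorm(1, cfg$antidromic_latency_ms,
                              cfg$antidromic_jitter_ms)) / 1000
          spikes <- sort(c(spikes, lat))
        }
        k <- k + 1L
        out[[k]] <- if (length(spikes)) {
          data.frame(unit = u, trial = tr, lpd = cfg$lpd_levels[li],
                     time = spikes)
        } else NULL
      }
    }
  }
  events <- do.call(rbind, out)
  if (is.null(events)) {
    events <- data.frame(unit = integer(), trial = integer(),
                         lpd = numeric(), time = numeric())
  }
  structure(list(
    events = events,
    unit_index = split(seq_len(nrow(events)), events$unit),
    protocol = list(pre_s = cfg$pre_s, light_s = cfg$light_s,
                    post_s = cfg$post_s, n_trials = cfg$n_trials,
                    lpd_levels = cfg$lpd_levels),
    truth = list(baseline_rate_hz = r0,
                 responsive = responsive,
                 suppression_fraction = s_levels,
                 rebound_gain = g, rebound_tau_s = cfg$rebound_tau_s,
                 antidromic_prob = cfg$antidromic_prob,
                 antidromic_latency_ms = cfg$antidromic_latency_ms),
    seed = cfg$seed), class = "spike_dataset")
}

#' Generate a synthetic per-frame pixel-change trace
#'
#' Emulates the changed-pixel counts a frame-differencing tracker produces:
#' high counts while the animal moves, near-zero counts inside scheduled
#' freezing bouts, optionally plus a patch-cord artifact component that a
#' mouse-body ROI would exclude. Ground-truth frame labels are attached.
#'
#' @param cfg a [sim_config()]; uses `session_s`, `fps`, `bout_schedule`,
#'   the motion/still noise levels and `cord_artifact`.
#' @return a [pixel_trace()] with attribute `truth` (logical freezing label
#'   per frame).
#' @export
gen_pixel_trace <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg$seed, 2L))
  n <- round(cfg$session_s * cfg$fps)
  frames_t <- (seq_len(n) - 1) / cfg$fps
  frozen <- rep(FALSE, n)
  for (b in cfg$bout_schedule) {
    frozen[frames_t >= b[1] & frames_t < b[2]] <- TRUE
  }
  vals <- numeric(n)
  vals[!frozen] <- pmax(0, rnorm(sum(!frozen), cfg$motion_px, cfg$motion_sd_px))
  vals[frozen] <- pmax(0, rnorm(sum(frozen), cfg$still_px, cfg$still_sd_px))
  if (cfg$cord_artifact) {
    # sporadic cord swings; these frames would be excluded by a body ROI
    swing <- runif(n) < 0.05
    vals[swing] <- vals[swing] + abs(rnorm(sum(swing), 2000, 500))
  }
  vals[1] <- 0  # first frame has no predecessor
  # traces emulate full-resolution video (512 x 384), independent of the
  # small rendered frame_shape used for synthetic stacks
  tr <- pixel_trace(vals, fps = cfg$fps, frame_pixels = 196608L,
                    roi_mode = "global")
  attr(tr, "truth") <- frozen
  tr
}

#' Render a synthetic grayscale frame stack
#'
#' Draws a disc-shaped "mouse" blob performing a random walk in the lower part
#' of the frame (stationary during scheduled freezing bouts) and, optionally,
#' a "patch-cord" line segment oscillating in a band along the top edge that
#' never overlaps the blob region. The disjoint supports let ROI-restricted
#' and global pixel-change traces be compared exactly.
#'
#' @param cfg a [sim_config()]; `frame_shape` must be at least 64 x 64.
#' @param n_frames number of frames (default `session_s * fps`).
#' @param blob_radius_px radius of the mouse blob.
#' @param step_px random-walk step per frame outside bouts.
#' @return an integer array (height x width x frames) of 8-bit values with
#'   attributes `truth` (frozen label per frame) and `centers` (blob centers).
#' @export
gen_frame_stack <- function(cfg, n_frames = NULL, blob_radius_px = 6,
                            step_px = 2) {
  stopifnot(inherits(cfg, "sim_config"))
  h <- cfg$frame_shape[1]; w <- cfg$frame_shape[2]
  stop_if_not(h >= 64 && w >= 64, "frame_shape must be at least 64 x 64")
  stop_if_not(2 * blob_radius_px < min(h, w),
              "blob diameter must be smaller than the frame")
  set.seed(substream_seed(cfg$seed, 3L))
  n <- n_frames %||% round(cfg$session_s * cfg$fps)
  frames_t <- (seq_len(n) - 1) / cfg$fps
  frozen <- rep(FALSE, n)
  for (b in cfg$bout_schedule) {
    frozen[frames_t >= b[1] & frames_t < b[2]] <- TRUE
  }
  cord_band <- 8L                     # rows 1..8 reserved for the cord
  ymin <- cord_band + blob_radius_px + 2
  ymax <- h - blob_radius_px - 1
  xmin <- blob_radius_px + 2
  xmax <- w - blob_radius_px - 1
  cy <- round((ymin + ymax) / 2); cx <- round((xmin + xmax) / 2)
  stack <- array(0L, dim = c(h, w, n))
  centers <- matrix(NA_real_, n, 2)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  for (f in seq_len(n)) {
    if (f > 1 && !frozen[f]) {
      # always take a real step (no zero move), respecting the walls
      repeat {
        ny <- min(ymax, max(ymin, cy + sample(c(-step_px, 0, step_px), 1)))
        nx <- min(xmax, max(xmin, cx + sample(c(-step_px, 0, step_px), 1)))
        if (ny != cy || nx != cx) break
      }
      cy <- ny; cx <- nx
    }
    img <- matrix(0L, h, w)
    img[(ys - cy)^2 + (xs - cx)^2 <= blob_radius_px^2] <- 200L
    if (cfg$cord_artifact) {
      col0 <- 1 + ((f * 3) %% (w - 12))   # cord sweeps along the top band
      img[3:6, col0:(col0 + 11)] <- 150L
    }
    stack[, , f] <- img
    centers[f, ] <- c(cy, cx)
  }
  attr(stack, "truth") <- frozen
  attr(stack, "centers") <- centers
  attr(stack, "cord_band_rows") <- if (cfg$cord_artifact) seq_len(cord_band) else integer()
  stack
}

#' Generate a synthetic voltage-clamp current trace
#'
#' `kind = "photocurrent"`: mono-exponential onset toward the stationary
#' current given by the saturation law I_ss = i_max * lpd / (epd50 + lpd),
#' then mono-exponential closure with `tau_off_s` after light offset.
#' `kind = "epsc"`: a delayed difference-of-exponentials deflection of given
#' amplitude after a brief light pulse. Gaussian noise of SD `noise_sd_pa` is
#' added in both cases.
#'
#' @param kind "photocurrent" or "epsc".
#' @param params named list; photocurrent: `i_max`, `epd50`, `lpd`,
#'   `tau_on_s`, `tau_off_s`, `baseline_pa`, `pre_s`, `pulse_s`, `post_s`;
#'   epsc: `amplitude_pa`, `latency_s`, `rise_s`, `decay_s`, `light_t`,
#'   `duration_s`, `baseline_pa`. Common: `noise_sd_pa`, `sample_rate_hz`
#'   (default 20000), `seed`, `v_hold_mv`, `wavelength_nm`.
#' @return a [current_trace()].
#' @export
gen_current_trace <- function(kind = c("photocurrent", "epsc"), params = list()) {
  kind <- match.arg(kind)
  p <- utils::modifyList(list(
    sample_rate_hz = 20000, noise_sd_pa = 0, seed = 1L, v_hold_mv = -35,
    wavelength_nm = 470, baseline_pa = 0), params)
  stop_if_not(p$sample_rate_hz > 0, "sample rate must be positive")
  set.seed(substream_seed(p$seed, 4L))
  dt <- 1 / p$sample_rate_hz
  if (kind == "photocurrent") {
    p <- utils::modifyList(list(i_max = 1000, epd50 = 0.05, lpd = 1,
                                tau_on_s = 0.002, tau_off_s = 0.010,
                                pre_s = 0.1, pulse_s = 1, post_s = 0.2), p)
    stop_if_not(p$tau_on_s > 0 && p$tau_off_s > 0, "tau must be positive")
    t <- seq(0, p$pre_s + p$pulse_s + p$post_s - dt, by = dt)
    on <- p$pre_s; off <- p$pre_s + p$pulse_s
    i_ss <- p$i_max * p$lpd / (p$epd50 + p$lpd)
    i <- rep(p$baseline_pa, length(t))
    dur <- t >= on & t < off
    i[dur] <- p$baseline_pa + i_ss * (1 - exp(-(t[dur] - on) / p$tau_on_s))
    i_off <- i_ss * (1 - exp(-p$pulse_s / p$tau_on_s))
    after <- t >= off
    i[after] <- p$baseline_pa + i_off * exp(-(t[after] - off) / p$tau_off_s)
    epochs <- data.frame(on = on, off = off, lpd = p$lpd,
                         wavelength = p$wavelength_nm)
  } else {
    p <- utils::modifyList(list(amplitude_pa = 150, latency_s = 0.008,
                                rise_s = 0.001, decay_s = 0.004,
                                light_t = 0.05, duration_s = 0.2), p)
    stop_if_not(p$rise_s > 0 && p$decay_s > 0 && p$decay_s > p$rise_s,
                "need 0 < rise < decay")
    t <- seq(0, p$duration_s - dt, by = dt)
    t0 <- p$light_t + p$latency_s
    shape <- ifelse(t >= t0,
                    exp(-(t - t0) / p$decay_s) - exp(-(t - t0) / p$rise_s), 0)
    tpk <- log(p$decay_s / p$rise_s) * p$rise_s * p$decay_s /
      (p$decay_s - p$rise_s)
    peak <- exp(-tpk / p$decay_s) - exp(-tpk / p$rise_s)
    i <- p$baseline_pa - p$amplitude_pa * shape / peak  # inward deflection
    epochs <- data.frame(on = p$light_t, off = p$light_t + 0.001, lpd = NA,
                         wavelength = p$wavelength_nm)
  }
  if (p$noise_sd_pa > 0) i <- i + rnorm(length(i), 0, p$noise_sd_pa)
  current_trace(t = t, i = i, sample_rate = p$sample_rate_hz,
                v_hold = p$v_hold_mv, light_epochs = epochs)
}

#' Generate a synthetic hemispheric nuclei-count table
#'
#' Per-region Poisson counts for both hemispheres and both stains. The
#' ipsilateral suppression factor applies to the c-Fos counts of expressing
#' regions only; DAPI counts are unaffected (cell density is preserved).
#' With factor f and symmetric baselines, the expected c-Fos lateralization
#' ratio of the expressing class is f / (1 + f).
#'
#' @param n_regions regions per class.
#' @param mean_count Poisson mean per (region, hemisphere).
#' @param suppression_factor multiplier on ipsilateral expressing-region c-Fos
#'   means (1 = no effect).
#' @param seed integer seed.
#' @return a data.frame (region, region_class, hemisphere, stain, count).
#' @export
gen_region_counts <- function(n_regions = 10, mean_count = 200,
                              suppression_factor = 1, seed = 1L) {
  stop_if_not(mean_count >= 0 && suppression_factor >= 0,
              "means must be non-negative")
  set.seed(substream_seed(seed, 5L))
  grid <- expand.grid(region = seq_len(2 * n_regions),
                      hemisphere = c("ipsi", "contra"),
                      stain = c("cfos", "dapi"),
                      stringsAsFactors = FALSE)
  grid$region_class <- ifelse(grid$region <= n_regions,
                              "expressing", "non-expressing")
  mu <- rep(mean_count, nrow(grid))
  hit <- grid$stain == "cfos" & grid$hemisphere == "ipsi" &
    grid$region_class == "expressing"
  mu[hit] <- mu[hit] * suppression_factor
  grid$count <- rpois(nrow(grid), mu)
  grid[, c("region", "region_class", "hemisphere", "stain", "count")]
}
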