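#' @section In vivo silencing analysis:
#' Per-unit and population quantification of optogenetic suppression and
#' antidromic spiking from sorted spike times. All windows are half-open with
#' light onset at t = 0; a spike exactly at 0 belongs to the light window.
#' @name acr-ephys
NULL

## events of one unit, using the dataset's per-unit row index when present
unit_events <- function(ds, unit) {
  idx <- ds$unit_index[[as.character(unit)]]
  if (is.null(idx)) ds$events[ds$events$unit == unit, , drop = FALSE]
  else ds$events[idx, , drop = FALSE]
}

## per-trial spike counts of one unit at one LPD inside a half-open window;
## trials without spikes contribute a 0
trial_counts <- function(ds, unit, lpd, window) {
  ev <- unit_events(ds, unit)
  sel <- ev$lpd == lpd & ev$time >= window[1] & ev$time < window[2]
  counts <- rep(0, ds$protocol$n_trials)
  if (any(sel)) {
    tab <- table(factor(ev$trial[sel], levels = seq_len(ds$protocol$n_trials)))
    counts <- as.numeric(tab)
  }
  counts
}

#' Classify a unit as significantly light-suppressed
#'
#' Paired two-tailed t-test on per-trial spike counts between the 5 s
#' pre-light window `[-5, 0)` and the 5 s light window `[0, 5)`. A unit is
#' flagged suppressed when p < alpha AND the mean light count is below the
#' mean pre count (the directional condition prevents flagging units that
#' increased their rate). Zero-variance paired differences are handled
#' without error (all-zero differences give p = 1).
#'
#' @param ds a `spike_dataset`.
#' @param unit unit id.
#' @param lpd light power density level to analyze.
#' @param alpha significance level (default 0.05, two-tailed).
#' @param pre_window,light_window half-open comparison windows, s.
#' @return list (suppressed flag, p, mean_pre, mean_light).
#' @export
classify_suppressed <- function(ds, unit, lpd = ds$protocol$lpd_levels[1],
                                alpha = 0.05,
                                pre_window = c(-5, 0), light_window = c(0, 5)) {
  stop_if_not(ds$protocol$n_trials >= 2, "need at least 2 trials")
  pre <- trial_counts(ds, unit, lpd, pre_window)
  light <- trial_counts(ds, unit, lpd, light_window)
  tt <- paired_t(light, pre)
  list(suppressed = tt$p_value < alpha && mean(light) < mean(pre),
       p = tt$p_value, mean_pre = mean(pre), mean_light = mean(light))
}

#' Relative firing rate of a unit (light / pre-light)
#'
#' Pooled firing rate during the light window divided by the pooled rate in
#' the pre-light window. Undefined (NA with attribute `undefined`) when the
#' pre-light rate is zero; such units are excluded from population means.
#'
#' @inheritParams classify_suppressed
#' @return a single number, or NA when the pre-light rate is zero.
#' @export
relative_fr <- function(ds, unit, lpd = ds$protocol$lpd_levels[1],
                        pre_window = c(-5, 0), light_window = c(0, 5)) {
  pre <- sum(trial_counts(ds, unit, lpd, pre_window))
  light <- sum(trial_counts(ds, unit, lpd, light_window))
  pre_rate <- pre / (ds$protocol$n_trials * diff(pre_window))
  light_rate <- light / (ds$protocol$n_trials * diff(light_window))
  if (pre_rate == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  light_rate / pre_rate
}

#' Population PSTH of relative firing rate
#'
#' Peri-stimulus time histogram of the firing rate normalized per unit: each
#' unit's binned rate is divided by that unit's mean pre-light rate, then
#' averaged across units. Bins of width `bin_s` (default 100 ms) tile
#' `[-pre_s, light_s + post_s)`. Units with zero pre-light rate are excluded
#' (their number is reported via message).
#'
#' @param ds a `spike_dataset`.
#' @param units unit ids to include (default all units present).
#' @param lpd light power density level.
#' @param bin_s bin width, s.
#' @return data.frame (bin_start, bin_mid, rel_rate, n_units).
#' @export
psth_relative <- function(ds, units = NULL, lpd = ds$protocol$lpd_levels[1],
                          bin_s = 0.1) {
  stop_if_not(bin_s > 0, "bin_s must be positive")
  pr <- ds$protocol
  units <- units %||% sort(unique(ds$events$unit))
  breaks <- seq(-pr$pre_s, pr$light_s + pr$post_s, by = bin_s)
  nb <- length(breaks) - 1L
  acc <- numeric(nb)
  used <- 0L
  for (u in units) {
    pre_n <- sum(trial_counts(ds, u, lpd, c(-pr$pre_s, 0)))
    if (pre_n == 0) next
    pre_rate <- pre_n / (pr$n_trials * pr$pre_s)
    ev <- unit_events(ds, u)
    tt <- ev$time[ev$lpd == lpd &
                    ev$time >= breaks[1] & ev$time < breaks[nb + 1]]
    counts <- if (length(tt)) {
      tabulate(findInterval(tt, breaks, rightmost.closed = FALSE), nbins = nb)
    } else rep(0L, nb)
    rate <- counts / (pr$n_trials * bin_s)
    acc <- acc + rate / pre_rate
    used <- used + 1L
  }
  excluded <- length(units) - used
  if (excluded > 0)
    message(excluded, " unit(s) with zero pre-light rate excluded from PSTH")
  stop_if_not(used > 0, "no unit with nonzero pre-light rate")
  data.frame(bin_start = breaks[-(nb + 1)],
             bin_mid = breaks[-(nb + 1)] + bin_s / 2,
             rel_rate = acc / used, n_units = used)
}

#' Classify a unit as antidromically activated by a short light pulse
#'
#' Paired two-tailed t-test on per-trial spike counts between the 20 ms
#' pre-light window `[-20, 0)` ms and the 20 ms window `[0, 20)` ms starting
#' at the onset of the short (5 ms) light pulse. Flagged when p < alpha AND
#' the mean light-window count exceeds the mean pre count. The mean first-
#' spike latency is averaged over trials containing at least one spike in the
#' light window; it is NA when no trial responds.
#'
#' @inheritParams classify_suppressed
#' @param window_ms analysis window length, ms (default 20).
#' @return list (antidromic flag, p, mean_latency_ms, n_responsive_trials).
#' @export
classify_antidromic <- function(ds, unit, lpd = ds$protocol$lpd_levels[1],
                                alpha = 0.05, window_ms = 20) {
  w <- window_ms / 1000
  pre <- trial_counts(ds, unit, lpd, c(-w, 0))
  light <- trial_counts(ds, unit, lpd, c(0, w))
  tt <- paired_t(light, pre)
  flag <- tt$p_value < alpha && mean(light) > mean(pre)
  ev <- unit_events(ds, unit)
  sel <- ev$lpd == lpd & ev$time >= 0 & ev$time < w
  lat <- NA_real_
  n_resp <- 0L
  if (any(sel)) {
    first <- tapply(ev$time[sel], ev$trial[sel], min)
    lat <- mean(first) * 1000
    n_resp <- length(first)
  }
  list(antidromic = flag, p = tt$p_value, mean_latency_ms = lat,
       n_responsive_trials = n_resp)
}

#' Order units by mean first-spike latency
#'
#' Ascending by latency, ties broken by unit id — the ordering used to
#' arrange antidromic raster plots from shortest to longest latency.
#'
#' @param latency_table data.frame with columns `unit` and `mean_latency_ms`.
#' @return the table reordered; rows with undefined latency are dropped.
#' @export
latency_order <- function(latency_table) {
  stop_if_not(all(c("unit", "mean_latency_ms") %in% names(latency_table)),
              "need columns unit and mean_latency_ms")
  tab <- latency_table[!is.na(latency_table$mean_latency_ms), , drop = FALSE]
  tab[order(tab$mean_latency_ms, tab$unit), , drop = FALSE]
}

#' Population summary and construct comparison of classified units
#'
#' Fractions of flagged units per group (e.g. opsin construct per light power
#' density) and pairwise 2x2 group comparisons, delegated to [chi2_2x2()]
#' when all cells are positive and to [fisher_exact_2x2()] when any cell is
#' zero.
#'
#' @param flags logical vector of per-unit flags.
#' @param group factor assigning each unit to a construct/group.
#' @return list with `fractions` (data.frame group, n, n_flagged, fraction)
#'   and `comparisons` (data.frame of pairwise statistics).
#' @export
population_summary <- function(flags, group) {
  group <- as.factor(group)
  stop_if_not(length(flags) == length(group), "flags and group lengths differ")
  stop_if_not(all(table(group) > 0), "empty group")
  n <- as.vector(table(group))
  nf <- as.vector(tapply(flags, group, sum))
  fractions <- data.frame(group = levels(group), n = n, n_flagged = nf,
                          fraction = nf / n)
  combs <- if (nlevels(group) >= 2) utils::combn(nlevels(group), 2) else
    matrix(integer(), 2, 0)
  comparisons <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
    i1 <- combs[1, j]; i2 <- combs[2, j]
    a <- nf[i1]; b <- n[i1] - nf[i1]; c <- nf[i2]; d <- n[i2] - nf[i2]
    res <- if (all(c(a, b, c, d) > 0)) chi2_2x2(a, b, c, d) else
      fisher_exact_2x2(a, b, c, d)
    data.frame(group1 = levels(group)[i1], group2 = levels(group)[i2],
               method = res$method, statistic = res$statistic,
               p = res$p_value)
  }))
  list(fractions = fractions, comparisons = comparisons)
}
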