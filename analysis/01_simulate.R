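#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input modality used by the downstream
# analyses and write them as plain-text tables under results/synthetic/.
# All randomness flows from one seed (--seed, default 1).

suppressMessages(library(acrquant))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if ("--seed" %in% args) args[which(args == "--seed") + 1] else 1)
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("== simulating with seed ", seed, " ==")

# two cohorts of units emulating an untargeted vs a soma-targeted construct:
# the soma-targeted one suppresses a larger fraction of its rate at every LPD
lpds <- c(0.125, 0.25, 0.5, 1)
# within each cohort only a fraction of units expresses functional opsin;
# responsive units are strongly suppressed, the soma-targeted construct
# recruits more of the population
cohorts <- list(
  GtACR2   = sim_config(seed = seed,      n_units = 100, baseline_rate_hz = 5,
                        rate_sdlog = 0.4, n_trials = 10, lpd_levels = lpds,
                        suppression_fraction = c(0.5, 0.65, 0.8, 0.8),
                        responsive_fraction = 0.40,
                        rebound_gain = 0.8, post_s = 2),
  stGtACR2 = sim_config(seed = seed + 1,  n_units = 98, baseline_rate_hz = 5,
                        rate_sdlog = 0.4, n_trials = 10, lpd_levels = lpds,
                        suppression_fraction = c(0.65, 0.8, 0.85, 0.85),
                        responsive_fraction = 0.65,
                        rebound_gain = 0.8, post_s = 2))
for (nm in names(cohorts)) {
  ds <- gen_spike_dataset(cohorts[[nm]])
  write.csv(ds$events, file.path(out, paste0("spikes_", nm, ".csv")),
            row.names = FALSE)
  message(sprintf("  %s: %d spikes from %d units at %d LPDs", nm,
                  nrow(ds$events), cohorts[[nm]]$n_units, length(lpds)))
}

# a behavioral session with scheduled freezing bouts
beh <- sim_config(seed = seed, session_s = 300,
                  bout_schedule = list(c(40, 55), c(90, 92), c(120, 140),
                                       c(200, 230), c(260, 263)))
tr <- gen_pixel_trace(beh)
write.csv(data.frame(frame = seq_along(tr$values) - 1, changed_px = tr$values,
                     frozen_truth = attr(tr, "truth")),
          file.path(out, "pixel_trace.csv"), row.names = FALSE)
message(sprintf("  behavior: %d frames, %.1f%% truly frozen",
                length(tr$values), 100 * mean(attr(tr, "truth"))))

# photocurrent traces across light power densities (per synthetic cell)
lpd_grid <- c(0.05, 0.1, 0.2, 0.5, 1, 2)
for (lpd in lpd_grid) {
  ct <- gen_current_trace("photocurrent",
                          list(i_max = 2000, epd50 = 0.1, lpd = lpd,
                               tau_off_s = 0.010, noise_sd_pa = 10,
                               seed = seed + round(1000 * lpd)))
  write.csv(data.frame(t_s = ct$t, i_pa = round(ct$i, 3)),
            file.path(out, sprintf("photocurrent_lpd%g.csv", lpd)),
            row.names = FALSE)
}
message("  photocurrents: ", length(lpd_grid), " traces (i_max 2000 pA, EPD50 0.1)")

# hemispheric nuclei counts for 7 synthetic animals, ipsi c-Fos suppressed
for (animal in 1:7) {
  tab <- gen_region_counts(n_regions = 12, mean_count = 250,
                           suppression_factor = 0.45, seed = seed + animal)
  tab$animal <- animal
  write.csv(tab, file.path(out, sprintf("region_counts_animal%d.csv", animal)),
            row.names = FALSE)
}
message("  histology: 7 animals x 24 regions x 2 stains")
message("done; outputs in ", out)
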