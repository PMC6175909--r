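#!/usr/bin/env Rscript
# Stage 4: photocurrent quantification on the simulated voltage-clamp traces:
# stationary currents per LPD, the saturation (EPD50) fit, closing kinetics,
# and an EPSC amplitude measurement. Reads results/synthetic/, writes
# results/biophys/.

suppressMessages(library(acrquant))
out <- "results/biophys"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

files <- list.files("results/synthetic", pattern = "^photocurrent_lpd",
                    full.names = TRUE)
pts <- do.call(rbind, lapply(files, function(f) {
  lpd <- as.numeric(sub(".*lpd([0-9.]+)\\.csv$", "\\1", f))
  d <- read.csv(f)
  tr <- current_trace(d$t_s, d$i_pa, sample_rate = 20000,
                      light_epochs = data.frame(on = 0.1, off = 1.1,
                                                lpd = lpd, wavelength = 470))
  data.frame(lpd = lpd, i = stationary_current(tr),
             peak = peak_current(tr),
             tau_off_ms = fit_tau_off(tr)$tau_off * 1000)
}))
pts <- pts[order(pts$lpd), ]
write.csv(pts, file.path(out, "stationary_currents.csv"), row.names = FALSE)
message("stationary photocurrents (pA) by LPD:")
print(pts)

sat <- fit_epd50(pts[, c("lpd", "i")])
message(sprintf("saturation fit: I_max = %.0f pA, EPD50 = %.3f mW mm^-2 (truth 2000 / 0.100)",
                sat$I_max, sat$EPD50))
message(sprintf("closing kinetics: median tau_off = %.2f ms (truth 10.00)",
                median(pts$tau_off_ms)))
write.csv(data.frame(I_max = sat$I_max, EPD50 = sat$EPD50,
                     median_tau_off_ms = median(pts$tau_off_ms)),
          file.path(out, "fits.csv"), row.names = FALSE)

# EPSC amplitude from a fresh synthetic synaptic trace
etr <- gen_current_trace("epsc", list(amplitude_pa = 150, noise_sd_pa = 5,
                                      seed = 11))
amp <- epsc_amplitude(etr)
message(sprintf("EPSC amplitude: %.1f pA (truth 150)", amp))
write.csv(data.frame(epsc_amplitude_pa = amp),
          file.path(out, "epsc.csv"), row.names = FALSE)
message("done; outputs in ", out)
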