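#!/usr/bin/env Rscript
# Stage 2: freezing classification of the simulated behavioral session and
# per-CS-window freezing percentages. Reads results/synthetic/pixel_trace.csv
# (run 01_simulate.R first), writes results/freezing/.

suppressMessages(library(acrquant))
out <- "results/freezing"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

raw <- read.csv("results/synthetic/pixel_trace.csv")
tr <- pixel_trace(raw$changed_px, fps = 25)
sm <- smooth_trace(tr, sigma_frames = 3)
res <- detect_freezing(sm, threshold_px = 983,
                       min_run_frames = min_run_from_duration(1.5, 25))

acc <- mean(res$frame_labels == raw$frozen_truth)
message(sprintf("freezing: %d bouts detected, frame accuracy vs truth %.3f",
                nrow(res$bouts), acc))
write.csv(as.data.frame(res$bouts), file.path(out, "bouts.csv"),
          row.names = FALSE)

# CS windows every 60 s, as in an extinction-style session
prot <- session_protocol(cs_starts_s = seq(30, 270, by = 60),
                         cs_duration_s = 30, phase_n = 2)
pct <- percent_freezing(res, prot)
write.csv(pct, file.path(out, "percent_freezing.csv"), row.names = FALSE)
write.csv(attr(pct, "phases"), file.path(out, "phase_means.csv"),
          row.names = FALSE)
message("per-window percentages:")
print(pct[pct$window == "cs", c("index", "start_s", "percent")])
message("done; outputs in ", out)
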