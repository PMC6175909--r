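#!/usr/bin/env Rscript
# Stage 6: hemispheric lateralization ratios per simulated animal and the
# paired comparison between expressing and non-expressing region classes.
# Reads results/synthetic/region_counts_animal*.csv, writes
# results/histology/.

suppressMessages(library(acrquant))
out <- "results/histology"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

files <- list.files("results/synthetic", pattern = "^region_counts_animal",
                    full.names = TRUE)
ratios <- do.call(rbind, lapply(files, function(f) {
  tab <- read.csv(f)
  d <- dapi_cr_er_ratio(tab)
  data.frame(animal = tab$animal[1],
             cfos_expressing = lateralization_ratio(tab, "expressing", "cfos"),
             cfos_nonexpressing = lateralization_ratio(tab, "non-expressing",
                                                       "cfos"),
             dapi_cr = d$cr, dapi_er = d$er)
}))
ratios <- ratios[order(ratios$animal), ]
write.csv(ratios, file.path(out, "lateralization_ratios.csv"),
          row.names = FALSE)
message("per-animal lateralization ratios:")
print(ratios, digits = 3)

# c-Fos: expressing class vs the 0.5 no-effect value, via paired comparison
# against the non-expressing class of the same animals
tt <- paired_t(ratios$cfos_expressing, ratios$cfos_nonexpressing)
message(sprintf("c-Fos expressing vs non-expressing: t = %.2f, p = %.3g",
                tt$statistic, tt$p_value))
# DAPI control: no class difference expected
td <- paired_t(ratios$dapi_er, ratios$dapi_cr)
message(sprintf("DAPI ER vs CR (control): t = %.2f, p = %.3g",
                td$statistic, td$p_value))
write.csv(data.frame(contrast = c("cfos_er_vs_cr", "dapi_er_vs_cr"),
                     t = c(tt$statistic, td$statistic),
                     p = c(tt$p_value, td$p_value)),
          file.path(out, "paired_tests.csv"), row.names = FALSE)
message("done; outputs in ", out)
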