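#' @section Histology-derived metrics:
#' Scalar quantification of histological outcomes: hemispheric lateralization
#' ratios of nuclei counts and expression-localization indices. Nuclei
#' detection and image segmentation are out of scope; counts and intensities
#' are inputs.
#' @name acr-quantify
NULL

check_region_table <- function(table) {
  need <- c("region", "region_class", "hemisphere", "stain", "count")
  stop_if_not(is.data.frame(table) && all(need %in% names(table)),
              paste("table needs columns:", paste(need, collapse = ", ")))
  stop_if_not(all(table$count >= 0 & table$count == round(table$count)),
              "counts must be non-negative integers")
  stop_if_not(all(table$hemisphere %in% c("ipsi", "contra")),
              "hemisphere must be ipsi or contra")
}

#' Hemispheric lateralization ratio of nuclei counts
#'
#' Ratio of summed ipsilateral counts to summed ipsilateral + contralateral
#' counts over the regions of one class:
#' sum(ipsi) / (sum(ipsi) + sum(contra)), in `[0, 1]`. A value of 0.5 means
#' equal counts across hemispheres; 0 means all nuclei contralateral. Pooling
#' counts before the ratio (rather than averaging per-region ratios) is the
#' default; set `per_region = TRUE` for the mean of per-region ratios.
#'
#' @param table region-count table (region, region_class, hemisphere, stain,
#'   count).
#' @param region_class "expressing" or "non-expressing".
#' @param stain "cfos" (default) or "dapi".
#' @param per_region average per-region ratios instead of pooling counts.
#' @return ratio in `[0, 1]`, or NA with attribute `undefined` when the
#'   summed denominator is zero.
#' @export
lateralization_ratio <- function(table, region_class, stain = "cfos",
                                 per_region = FALSE) {
  check_region_table(table)
  sel <- table$region_class == region_class & table$stain == stain
  stop_if_not(any(sel), "no rows for that class/stain")
  sub <- table[sel, ]
  if (per_region) {
    ipsi <- tapply(sub$count[sub$hemisphere == "ipsi"],
                   sub$region[sub$hemisphere == "ipsi"], sum)
    contra <- tapply(sub$count[sub$hemisphere == "contra"],
                     sub$region[sub$hemisphere == "contra"], sum)
    stop_if_not(identical(names(ipsi), names(contra)),
                "each ipsi region needs a homologous contra row")
    tot <- ipsi + contra
    if (any(tot == 0)) return(structure(NA_real_, undefined = TRUE))
    return(mean(ipsi / tot))
  }
  si <- sum(sub$count[sub$hemisphere == "ipsi"])
  sc <- sum(sub$count[sub$hemisphere == "contra"])
  if (si + sc == 0) return(structure(NA_real_, undefined = TRUE))
  si / (si + sc)
}

#' DAPI lateralization ratios for control and expressing region classes
#'
#' The lateralization normalization applied to DAPI nuclei counts per region
#' class — the control for opsin-induced cell loss. Returns the ratio for
#' non-expressing (CR) and expressing (ER) ipsilateral region classes; equal
#' cell density across hemispheres puts both near 0.5. The comparison
#' statistic across animals is [paired_t()].
#'
#' @param table region-count table including `stain == "dapi"` rows.
#' @return list (cr, er) of ratios.
#' @export
dapi_cr_er_ratio <- function(table) {
  list(cr = lateralization_ratio(table, "non-expressing", stain = "dapi"),
       er = lateralization_ratio(table, "expressing", stain = "dapi"))
}

#' Soma-restriction index from a fluorescence profile
#'
#' Mean layer-1 fluorescence normalized by the mean fluorescence at the
#' injection center; lower values indicate stronger restriction of expression
#' to the somatic compartment (less neurite-borne signal reaching layer 1).
#'
#' @param layer1 layer-1 intensity samples (arbitrary units).
#' @param center injection-center intensity samples (same acquisition scale).
#' @return dimensionless index (mean(layer1)/mean(center)), NA when the
#'   center mean is zero.
#' @export
layer1_restriction_index <- function(layer1, center) {
  stop_if_not(length(layer1) >= 1 && length(center) >= 1,
              "both regions need samples")
  stop_if_not(all(layer1 >= 0) && all(center >= 0),
              "intensities must be non-negative")
  mc <- mean(center)
  if (mc == 0) return(structure(NA_real_, undefined = TRUE))
  mean(layer1) / mc
}

#' Normalize values to a reference mean (fold change)
#'
#' `values / reference_mean` — e.g. fluorescence intensities expressed as
#' fold of a reference condition's average.
#'
#' @param values numeric vector.
#' @param reference_mean positive scalar reference.
#' @return fold values.
#' @export
normalize_to_reference <- function(values, reference_mean) {
  stop_if_not(length(reference_mean) == 1 && reference_mean > 0,
              "reference mean must be a positive scalar")
  values / reference_mean
}
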