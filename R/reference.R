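#' Reference unit counts of the in vivo silencing dataset
#'
#' The published per-construct unit tallies used for construct comparisons:
#' fractions of units significantly suppressed during 5 s illumination at
#' each light power density (GtACR2: n = 100 units; soma-targeted stGtACR2:
#' n = 98), and fractions of units with antidromic responses to 5 ms pulses
#' delivered to distal axons (GtACR2: 14 of 73; stGtACR2: 2 of 70). Counts at
#' the four light powers are reconstructed from the reported percentages as
#' `round(pct * n / 100)`.
#'
#' @return data.frame with one row per comparison: `comparison`,
#'   `lpd_mw_mm2`, and the 2x2 cells `a`, `b` (construct 1 flagged / not) and
#'   `c`, `d` (construct 2 flagged / not).
#' @export
reference_unit_counts <- function() {
  n1 <- 100L; n2 <- 98L
  pct1 <- c(21, 29, 43, 35)          # suppressed units, GtACR2
  pct2 <- c(52, 61, 61, 56)          # suppressed units, stGtACR2
  a <- as.integer(round(pct1 * n1 / 100))
  c_ <- as.integer(round(pct2 * n2 / 100))
  out <- data.frame(
    comparison = c(rep("suppressed_GtACR2_vs_stGtACR2", 4),
                   "antidromic_NAc_GtACR2_vs_stGtACR2"),
    lpd_mw_mm2 = c(0.125, 0.25, 0.5, 1, 1),
    a = c(a, 14L), b = c(n1 - a, 73L - 14L),
    c = c(c_, 2L), d = c(n2 - c_, 70L - 2L))
  out
}

#' Recompute the construct-comparison contingency statistics
#'
#' Applies [chi2_2x2()] to every row of [reference_unit_counts()], returning
#' the chi-square statistics and p-values for the five construct comparisons.
#'
#' @return the counts table with `chi2` and `p` columns appended.
#' @export
contingency_reproduction <- function() {
  tab <- reference_unit_counts()
  res <- lapply(seq_len(nrow(tab)),
                function(i) chi2_2x2(tab$a[i], tab$b[i], tab$c[i], tab$d[i]))
  tab$chi2 <- vapply(res, function(r) r$statistic, numeric(1))
  tab$p <- vapply(res, function(r) r$p_value, numeric(1))
  tab
}
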