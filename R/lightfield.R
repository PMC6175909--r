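#' Analytical tissue-optics model for fiber-delivered light
#'
#' Parameters of the analytical irradiance-attenuation model used to estimate
#' light power density at depth below an optical fiber: a geometric
#' cone-spread term derived from the fiber radius, numerical aperture and
#' tissue refractive index, multiplied by a Kubelka-Munk-type scattering term
#' and (optionally) Beer-Lambert absorption. The scattering coefficient
#' scales with wavelength as a power law around a reference wavelength, so
#' transmittance increases toward longer wavelengths. All constants are
#' editable; the defaults are representative textbook values for rodent gray
#' matter, not measurements of any particular preparation.
#'
#' @param fiber_radius_mm fiber core radius, mm.
#' @param numerical_aperture fiber NA (dimensionless).
#' @param tissue_index refractive index of brain tissue.
#' @param scatter_coef_mm scattering coefficient S at `scatter_ref_nm`,
#'   mm^-1.
#' @param scatter_ref_nm reference wavelength for S, nm.
#' @param scatter_exponent power-law exponent b in S(lambda) =
#'   S_ref (lambda/lambda_ref)^-b.
#' @param absorb_coef_mm absorption coefficient, mm^-1 (default 0).
#' @return a `tissue_optics_model` object.
#' @export
tissue_optics_model <- function(fiber_radius_mm = 0.1,
                                numerical_aperture = 0.37,
                                tissue_index = 1.36,
                                scatter_coef_mm = 11.2,
                                scatter_ref_nm = 473,
                                scatter_exponent = 1.4,
                                absorb_coef_mm = 0) {
  stop_if_not(all(c(fiber_radius_mm, numerical_aperture, tissue_index,
                    scatter_coef_mm, scatter_ref_nm) > 0),
              "model parameters must be positive")
  stop_if_not(tissue_index > numerical_aperture,
              "tissue_index must exceed the numerical aperture")
  stop_if_not(absorb_coef_mm >= 0 && scatter_exponent >= 0,
              "absorption and scattering exponent must be >= 0")
  structure(list(fiber_radius_mm = fiber_radius_mm,
                 numerical_aperture = numerical_aperture,
                 tissue_index = tissue_index,
                 scatter_coef_mm = scatter_coef_mm,
                 scatter_ref_nm = scatter_ref_nm,
                 scatter_exponent = scatter_exponent,
                 absorb_coef_mm = absorb_coef_mm,
                 variant = "cone-kubelka-munk"),
            class = "tissue_optics_model")
}

## geometric cone-spread attenuation: rho = r sqrt((n/NA)^2 - 1),
## I(z)/I(0) = rho^2 / (z + rho)^2
geometric_term <- function(model, z_mm) {
  rho <- model$fiber_radius_mm *
    sqrt((model$tissue_index / model$numerical_aperture)^2 - 1)
  rho^2 / (z_mm + rho)^2
}

## scattering (Kubelka-Munk) x absorption attenuation at a wavelength
tissue_term <- function(model, z_mm, wavelength_nm) {
  s <- model$scatter_coef_mm *
    (wavelength_nm / model$scatter_ref_nm)^(-model$scatter_exponent)
  1 / (s * z_mm + 1) * exp(-model$absorb_coef_mm * z_mm)
}

#' Fractional irradiance at depth
#'
#' Fraction of the fiber-exit light power density remaining at depth `z_mm`:
#' the product of the geometric cone-spread term and the wavelength-dependent
#' scattering/absorption term. Equals 1 at z = 0 and decreases strictly
#' with depth.
#'
#' @param model a [tissue_optics_model()].
#' @param z_mm depth below the fiber tip, mm (>= 0; vectorized).
#' @param wavelength_nm light wavelength, nm.
#' @return dimensionless fraction in (0, 1].
#' @export
fractional_irradiance <- function(model, z_mm, wavelength_nm = 473) {
  stopifnot(inherits(model, "tissue_optics_model"))
  stop_if_not(all(z_mm >= 0), "depth must be >= 0")
  geometric_term(model, z_mm) * tissue_term(model, z_mm, wavelength_nm)
}

#' Light power density at depth
#'
#' `exit_lpd * fractional_irradiance(model, z, lambda)`; linear in the exit
#' light power density.
#'
#' @inheritParams fractional_irradiance
#' @param exit_lpd light power density exiting the fiber, mW mm^-2 (>= 0).
#' @return LPD at depth, mW mm^-2.
#' @export
lpd_at_depth <- function(model, exit_lpd, z_mm, wavelength_nm = 473) {
  stop_if_not(all(exit_lpd >= 0), "exit LPD must be >= 0")
  exit_lpd * fractional_irradiance(model, z_mm, wavelength_nm)
}

#' Opsin action spectrum
#'
#' Wavelength-to-relative-response table, peak-normalized to 1. Bundled
#' example spectra (see `system.file("extdata", package = "acrquant")`) are
#' synthetic unimodal stand-ins, not published measurements.
#'
#' @param wavelength_nm sampled wavelengths (>= 1 nm resolution recommended).
#' @param response relative responses (>= 0, not all zero).
#' @param opsin optional opsin label.
#' @return data.frame (wavelength_nm, response) with max response 1 and
#'   attribute `opsin`.
#' @export
action_spectrum <- function(wavelength_nm, response, opsin = NA_character_) {
  stop_if_not(length(wavelength_nm) == length(response) &&
                length(response) >= 2, "need matching vectors of length >= 2")
  stop_if_not(all(response >= 0) && max(response) > 0,
              "responses must be >= 0 with a positive peak")
  o <- order(wavelength_nm)
  out <- data.frame(wavelength_nm = wavelength_nm[o],
                    response = response[o] / max(response))
  if (min(out$wavelength_nm) > 400 || max(out$wavelength_nm) < 650)
    warning("spectrum does not cover the full 400-650 nm range")
  attr(out, "opsin") <- opsin
  class(out) <- c("action_spectrum", class(out))
  out
}

#' Read an action spectrum from a two-column CSV
#'
#' @param path CSV with columns `wavelength_nm` and `response`.
#' @param opsin optional opsin label (defaults to the file name).
#' @return an [action_spectrum()].
#' @export
read_action_spectrum <- function(path, opsin = NULL) {
  d <- utils::read.csv(path)
  stop_if_not(all(c("wavelength_nm", "response") %in% names(d)),
              "CSV must have columns wavelength_nm and response")
  action_spectrum(d$wavelength_nm, d$response,
                  opsin = opsin %||% sub("\\.csv$", "", basename(path)))
}

#' Depth-optimal excitation wavelength
#'
#' The wavelength maximizing the product of the opsin action spectrum and the
#' fractional irradiance at depth `z_mm`. At z = 0 the transmittance is flat
#' and the spectrum peak is returned; with scattering decreasing toward long
#' wavelengths the optimum red-shifts as depth grows.
#'
#' @param model a [tissue_optics_model()].
#' @param spectrum an [action_spectrum()] (or data.frame with columns
#'   `wavelength_nm`, `response`).
#' @param z_mm depth, mm.
#' @return the optimal wavelength, nm (with attribute `product` holding the
#'   full depth-weighted spectrum).
#' @export
optimal_wavelength <- function(model, spectrum, z_mm) {
  stop_if_not(is.data.frame(spectrum) && nrow(spectrum) > 0,
              "spectrum must be a non-empty table")
  prod <- spectrum$response *
    fractional_irradiance(model, z_mm, spectrum$wavelength_nm)
  best <- spectrum$wavelength_nm[which.max(prod)]
  structure(best, product = data.frame(wavelength_nm = spectrum$wavelength_nm,
                                       weighted = prod))
}
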