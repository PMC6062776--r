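#' Hemoglobin molar extinction spectrum
#'
#' Bundled molar extinction coefficients (M^-1 cm^-1) of oxy- and
#' deoxyhemoglobin at the two excitation laser wavelengths, on the
#' hemoglobin tetramer basis (64,500 g/mol), consistent with a whole-blood
#' tetramer concentration of ~2.3 mM.  Values are linear interpolations of
#' the standard tabulated compendium of hemoglobin extinction spectra to
#' 445 and 637 nm.  445 nm lies on the steep red flank of the Soret band,
#' so the extinction there is sensitive to the table and to a few nm of
#' wavelength; the Q-band tail at 637 nm is flat and robust.  Override
#' with your own table via [chromophore_spectrum()] or
#' [read_extinction_csv()].
#'
#' @param entries data frame with columns `wavelength_nm`, `eps_hbo2`,
#'   `eps_hb` (all positive, unique wavelengths).
#' @return An object of class `chromophore_spectrum`.
#' @examples
#' hemoglobin_extinction()
#' @export
chromophore_spectrum <- function(entries) {
  req <- c("wavelength_nm", "eps_hbo2", "eps_hb")
  if (!is.data.frame(entries) || !all(req %in% names(entries)))
    stop_param("'entries' needs columns wavelength_nm, eps_hbo2, eps_hb")
  if (anyDuplicated(entries$wavelength_nm) ||
      any(entries$wavelength_nm <= 0) ||
      any(entries$eps_hbo2 <= 0) || any(entries$eps_hb <= 0))
    stop_param("wavelengths must be unique/positive and extinctions positive")
  structure(list(entries = entries[req]), class = "chromophore_spectrum")
}

#' @rdname chromophore_spectrum
#' @export
hemoglobin_extinction <- function() {
  chromophore_spectrum(data.frame(
    wavelength_nm = c(445, 637),
    eps_hbo2      = c(68864, 458),
    eps_hb        = c(155588, 4256)))
}

#' Read an extinction override table from CSV
#'
#' @param path CSV with header `wavelength_nm, eps_hbo2, eps_hb`.
#' @return A [chromophore_spectrum()].
#' @export
read_extinction_csv <- function(path) {
  chromophore_spectrum(utils::read.csv(path))
}

#' Optical parameters of a surface vessel
#'
#' Assumes hemoglobin is the primary absorber in blood: total hemoglobin
#' concentration (tetramer molarity), arterial oxygen saturation, and the
#' optical path length through the vessel.
#'
#' @param hb_concentration hemoglobin concentration, mol/L (default
#'   2.3e-3, i.e. 2.3 mM).
#' @param sao2 oxygen saturation fraction in `[0, 1]` (default 0.95).
#' @param path_length path length through the vessel, cm (default 0.01,
#'   a 100-um arteriole).
#' @return An object of class `vessel_optics_params`.
#' @export
vessel_optics_params <- function(hb_concentration = 2.3e-3, sao2 = 0.95,
                                 path_length = 0.01) {
  if (!is.numeric(hb_concentration) || hb_concentration < 0)
    stop_param("'hb_concentration' must be non-negative (mol/L)")
  if (!is.numeric(sao2) || sao2 < 0 || sao2 > 1)
    stop_param("'sao2' must be a fraction in [0, 1]")
  if (!is.numeric(path_length) || path_length < 0)
    stop_param("'path_length' must be non-negative (cm)")
  structure(list(hb_concentration = hb_concentration, sao2 = sao2,
                 path_length = path_length),
            class = "vessel_optics_params")
}

#' Blood absorption coefficient at a wavelength
#'
#' Beer-Lambert absorption coefficient of blood modeled as a two-component
#' hemoglobin mixture:
#' `mu_a = ln(10) * C * (SaO2 * eps_HbO2 + (1 - SaO2) * eps_Hb)` in cm^-1.
#' The wavelength must be present in the spectrum exactly; no silent
#' interpolation is performed.
#'
#' @param spectrum a [chromophore_spectrum()].
#' @param params a [vessel_optics_params()].
#' @param wavelength wavelength in nm, present in the spectrum.
#' @return Absorption coefficient, cm^-1.
#' @export
absorption_coefficient <- function(spectrum, params, wavelength) {
  if (!inherits(spectrum, "chromophore_spectrum"))
    stop_param("'spectrum' must be a chromophore_spectrum")
  i <- match(wavelength, spectrum$entries$wavelength_nm)
  if (is.na(i))
    stop_param(sprintf(
      "wavelength %g nm not tabulated (no interpolation; supply a table entry)",
      wavelength))
  e <- spectrum$entries[i, ]
  log(10) * params$hb_concentration *
    (params$sao2 * e$eps_hbo2 + (1 - params$sao2) * e$eps_hb)
}

#' Beer-Lambert transmittance
#'
#' Fraction of incident light transmitted through an absorbing path,
#' `T = exp(-mu_a * L)`.  Scattering is neglected, so this is the most
#' conservative (largest) estimate of transmission through a vessel.
#'
#' @param mu_a absorption coefficient, cm^-1 (>= 0).
#' @param path_length path length, cm (>= 0).
#' @return Transmitted fraction in `(0, 1]`.
#' @export
transmittance <- function(mu_a, path_length) {
  if (any(mu_a < 0) || any(path_length < 0))
    stop_param("'mu_a' and 'path_length' must be non-negative")
  exp(-mu_a * path_length)
}

#' Transmittance through a surface vessel at a laser wavelength
#'
#' Convenience wrapper chaining [absorption_coefficient()] and
#' [transmittance()] for the vessel geometry in `params`.  With the
#' bundled extinction table and defaults (2.3 mM hemoglobin, 95 percent
#' SaO2, 100-um path), 637-nm light is almost fully transmitted (~96
#' percent) while 445-nm light is almost entirely absorbed within the
#' vessel (~1-2 percent transmitted).
#'
#' @param wavelength wavelength, nm.
#' @param params a [vessel_optics_params()].
#' @param spectrum a [chromophore_spectrum()]; default the bundled
#'   hemoglobin table.
#' @return Transmitted fraction.
#' @examples
#' vessel_transmittance(637)
#' vessel_transmittance(445)
#' @export
vessel_transmittance <- function(wavelength,
                                 params = vessel_optics_params(),
                                 spectrum = hemoglobin_extinction()) {
  transmittance(absorption_coefficient(spectrum, params, wavelength),
                params$path_length)
}
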