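#' Convert a molar concentration to a number density
#'
#' Multiplies by the Avogadro constant and converts litres to cubic
#' nanometres: `c [mol/L] * 6.02214076e23 / 1e24` molecules/nm^3.
#'
#' @param c concentration in mol/L (non-negative).
#' @return Number density in molecules/nm^3.
#' @examples
#' molar_to_number_density(0.03245) # 0.01954 molecules/nm^3
#' @export
molar_to_number_density <- function(c) {
  if (any(!is.finite(c)) || any(c < 0)) {
    stop("`c` must be non-negative", call. = FALSE)
  }
  c * .N_AVOGADRO / 1e24
}

#' Box length holding N particles at a given number density
#'
#' Edge of the cubic box with `N_total / concentration` volume:
#' `(N_total / concentration)^(1/3)`. Used by the fixed-concentration
#' system-size (R2) scans.
#'
#' @param N_total particle count (> 0).
#' @param concentration number density in molecules/nm^3 (> 0).
#' @return Box edge in nm.
#' @examples
#' derive_box_length(2, 0.01954)  # 4.678 nm
#' derive_box_length(12, 0.01954) # 8.500 nm
#' @export
derive_box_length <- function(N_total, concentration) {
  if (any(!is.finite(N_total)) || any(N_total <= 0) ||
      any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("`N_total` and `concentration` must be positive", call. = FALSE)
  }
  (N_total / concentration)^(1 / 3)
}
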