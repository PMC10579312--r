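# Ion-type arithmetic. All ions are singly charged; mass arithmetic
# includes the electron mass.

# label -> list(delta_mass applied to neutral M to obtain m/z, charge sign)
ION_TYPES <- list(
  "[M-H]-"  = list(delta = -1.0078250319 + 0.00054858, charge = -1L),
  "[M+H]+"  = list(delta = +1.0078250319 - 0.00054858, charge = +1L),
  "[M+Na]+" = list(delta = +22.98976928 - 0.00054858,  charge = +1L),
  "[M+Cl]-" = list(delta = +34.96885268 + 0.00054858,  charge = -1L),
  "M+."     = list(delta = -0.00054858,                charge = +1L)
)

# default ion-type set per ionization mode
MODE_ION_TYPES <- list(
  esi_neg  = c("[M-H]-", "[M+Cl]-"),
  esi_pos  = c("[M+H]+", "[M+Na]+"),
  appi_pos = c("[M+H]+", "M+.")
)

#' Supported ion-type labels
#' @return character vector of labels
#' @export
ion_type_labels <- function() names(ION_TYPES)

#' Default ion types for an ionization mode
#' @param mode `"esi_neg"`, `"esi_pos"` or `"appi_pos"`
#' @return character vector of ion-type labels
#' @export
default_ion_types <- function(mode) {
  if (!mode %in% names(MODE_ION_TYPES)) {
    stop("unknown ionization mode: ", mode)
  }
  MODE_ION_TYPES[[mode]]
}

ion_delta <- function(ion_type) {
  it <- ION_TYPES[[ion_type]]
  if (is.null(it)) stop("unknown ion type: ", ion_type)
  it$delta
}

#' m/z of an ion formed from a neutral monoisotopic mass
#'
#' @param neutral_mass neutral monoisotopic mass in Da
#' @param ion_type one of `"[M-H]-"`, `"[M+H]+"`, `"[M+Na]+"`, `"[M+Cl]-"`,
#'   `"M+."`
#' @return m/z in Da (charge 1)
#' @export
ion_mz <- function(neutral_mass, ion_type) {
  neutral_mass + ion_delta(ion_type)
}

#' Neutral monoisotopic mass from an observed m/z
#'
#' Inverts the adduct arithmetic, electron mass included: e.g. for
#' `[M-H]-`, `M = mz + 1.0078250 - 0.0005486`.
#'
#' @param mz observed m/z (Da, charge 1)
#' @param ion_type ion-type label
#' @return neutral monoisotopic mass in Da
#' @export
neutral_mass_from_mz <- function(mz, ion_type) {
  stopifnot(all(mz > 0))
  m <- mz - ion_delta(ion_type)
  if (any(m <= 0)) stop("ion arithmetic yields non-positive neutral mass")
  m
}
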