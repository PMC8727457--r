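#' Physical constants and unit conversions
#'
#' All structure-layer coordinates are in angstrom; energies are carried in
#' hartree internally and excitation energies are reported in eV. These
#' constants are the single point of truth for unit conversions in the
#' package.
#'
#' @name units
#' @keywords internal
NULL

## CODATA 2018
HARTREE_EV <- 27.211386245988   # eV per hartree
BOHR_PER_ANG <- 1.8897259886    # bohr per angstrom
HC_EV_NM <- 1239.84193          # h*c in eV * nm

#' Convert an excitation energy from eV to wavelength in nm
#'
#' Uses lambda = hc / E with hc = 1239.84193 eV nm.
#'
#' @param e Energy in eV; must be positive.
#' @return Wavelength in nm.
#' @examples
#' ev_to_nm(3.309)
#' @export
ev_to_nm <- function(e) {
  if (any(!is.finite(e)) || any(e <= 0)) {
    stop("ev_to_nm() needs positive finite energies in eV", call. = FALSE)
  }
  HC_EV_NM / e
}

#' Convert an energy from eV to hartree
#'
#' @param e Energy in eV.
#' @return Energy in hartree.
#' @examples
#' ev_to_hartree(27.211386245988)
#' @export
ev_to_hartree <- function(e) {
  if (any(!is.finite(e))) stop("ev_to_hartree() needs finite input", call. = FALSE)
  e / HARTREE_EV
}

#' Convert an energy from hartree to eV
#'
#' @param e Energy in hartree.
#' @return Energy in eV.
#' @export
hartree_to_ev <- function(e) {
  if (any(!is.finite(e))) stop("hartree_to_ev() needs finite input", call. = FALSE)
  e * HARTREE_EV
}
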