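#' Physical constants and unit conversions
#'
#' All internal geometry is in bohr; energies in eV unless noted.
#' @name units
#' @keywords internal
NULL

# CODATA-2018 values
BOHR_PER_ANGSTROM <- 1.8897259886
HARTREE_EV <- 27.211386245988
# E(eV) * lambda(nm) product
EV_NM <- 1239.841984

#' Convert Angstrom to bohr
#' @param x numeric, length in Angstrom
#' @return numeric, length in bohr
#' @export
ang2bohr <- function(x) x * BOHR_PER_ANGSTROM

#' Convert bohr to Angstrom
#' @param x numeric, length in bohr
#' @return numeric, length in Angstrom
#' @export
bohr2ang <- function(x) x / BOHR_PER_ANGSTROM
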