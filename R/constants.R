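#' Physical constants and unit conversions
#'
#' The package works in Angstrom / elementary charge / kJ/mol units.
#' `KE_COULOMB` is the Coulomb constant expressed in those units, i.e. the
#' energy in kJ/mol of two unit point charges 1 Angstrom apart.
#' Electronegativities (V) and hardnesses (V/e) convert to kJ/mol per e via
#' `EV_TO_KJMOL`; `HARTREE_TO_KJMOL` is used when expressing hartree-based
#' selection thresholds (e.g. an exchange-energy cutoff) in kJ/mol.
#'
#' @name constants
#' @aliases KE_COULOMB EV_TO_KJMOL HARTREE_TO_KJMOL
NULL

#' @rdname constants
#' @export
KE_COULOMB <- 1389.35458

#' @rdname constants
#' @export
EV_TO_KJMOL <- 96.4853

#' @rdname constants
#' @export
HARTREE_TO_KJMOL <- 2625.4996

# Bondi van der Waals radii (Angstrom), default source for grid construction
# and contact-distance generation; overridable per call.
.bondi <- c(
  H = 1.20, He = 1.40,
  Li = 1.82, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Na = 2.27, Mg = 1.73, P = 1.80, S = 1.80, Cl = 1.75,
  K = 2.75, Br = 1.85, I = 1.98
)

#' Look up van der Waals radii by element symbol
#'
#' Bondi radii; elements outside the table fall back to 1.7 Angstrom.
#'
#' @param element character vector of element symbols
#' @return numeric vector of radii in Angstrom
#' @export
vdw_radius <- function(element) {
  r <- .bondi[element]
  r[is.na(r)] <- 1.7
  unname(r)
}

# error function via the normal CDF (double precision accurate)
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
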