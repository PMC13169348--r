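# Physical constants and unit conversions used across the package.
# Internal conventions: energies in kcal/mol, coordinates in Angstrom,
# rotational constants in MHz, frequencies in cm^-1, temperatures in K.

#' @keywords internal
HARTREE_TO_KCAL <- 627.5094740631

#' Gas constant in kcal/(mol K)
#' @keywords internal
R_KCAL <- 1.987204e-3

# Gas constant, SI, J/(mol K)
R_SI <- 8.31446261815324

# rotational constant conversion: B [cm^-1] = ROT_CM1 / I [u Angstrom^2]
ROT_CM1 <- 16.857629

# 1 cm^-1 in MHz
CM1_TO_MHZ <- 29979.2458

# Planck constant (J s), Boltzmann constant (J/K), speed of light (cm/s),
# Avogadro number, atomic mass unit (kg)
H_PLANCK <- 6.62607015e-34
K_BOLTZ <- 1.380649e-23
C_LIGHT_CM <- 2.99792458e10
N_AVOGADRO <- 6.02214076e23
AMU_KG <- 1.66053906660e-27

# J/mol -> kcal/mol
J_MOL_TO_KCAL <- 1 / 4184

# u Angstrom^2 -> kg m^2
UA2_TO_KGM2 <- AMU_KG * 1e-20

# Most-abundant-isotope atomic masses (u), the standard convention for
# rotational constants. Covers the elements organic ensembles contain.
.ATOMIC_MASSES <- c(
  H  = 1.00782503207, D = 2.01410177812, He = 4.00260325413,
  Li = 7.0160034366,  Be = 9.012183065,  B  = 11.00930536,
  C  = 12.0,          N  = 14.0030740048, O = 15.9949146196,
  F  = 18.9984031627, Ne = 19.9924401762, Na = 22.9897692820,
  Mg = 23.985041697,  Al = 26.98153853,  Si = 27.97692653465,
  P  = 30.97376199842, S = 31.9720711744, Cl = 34.968852682,
  Ar = 39.9623831237, K  = 38.9637064864, Ca = 39.962590863,
  Sc = 44.95590828,   Ti = 47.94794198,  V  = 50.94395704,
  Cr = 51.94050623,   Mn = 54.93804391,  Fe = 55.93493633,
  Co = 58.93319429,   Ni = 57.93534241,  Cu = 62.92959772,
  Zn = 63.92914201,   Ga = 68.9255735,   Ge = 73.921177761,
  As = 74.92159457,   Se = 79.9165218,   Br = 78.9183376,
  Kr = 83.9114977282, Rb = 84.9117897379, Sr = 87.9056125,
  I  = 126.9044719,   Sn = 119.90220163, Sb = 120.903812,
  Te = 129.906222748, Xe = 131.9041550856
)

#' Look up most-abundant-isotope atomic masses
#'
#' @param symbols character vector of element symbols (case sensitive,
#'   standard capitalisation).
#' @return numeric vector of masses in unified atomic mass units.
#' @examples
#' atomic_masses(c("C", "H", "O"))
#' @export
atomic_masses <- function(symbols) {
  m <- .ATOMIC_MASSES[symbols]
  if (anyNA(m)) {
    bad <- unique(symbols[is.na(m)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(m)
}

#' Convert energies from Hartree to kcal/mol
#'
#' @param x numeric vector of energies in Hartree.
#' @return energies in kcal/mol.
#' @export
hartree_to_kcal <- function(x) x * HARTREE_TO_KCAL

#' Convert a Gaussian FWHM to its standard deviation
#'
#' sigma = gamma / (2 sqrt(2 ln 2)).
#'
#' @param gamma full width at half maximum.
#' @return standard deviation in the same units.
#' @export
fwhm_to_sigma <- function(gamma) gamma / (2 * sqrt(2 * log(2)))

#' Convert between nm and eV for electronic spectra
#'
#' Uses E(eV) = 1239.841984 / lambda(nm).
#'
#' @param x numeric vector.
#' @return the converted vector (the transform is its own inverse).
#' @export
nm_to_ev <- function(x) 1239.841984 / x
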