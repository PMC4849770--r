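# Physical constants (CODATA 2018) and atomic masses.
#
# Unit chain used for quasi-harmonic entropy:
#   covariance eigenvalues lambda are in amu * Angstrom^2;
#   lambda [kg m^2] = lambda * .amu_kg * 1e-20;
#   omega = sqrt(kB * T / lambda[kg m^2])  [rad/s];
#   molar entropy S = R * sum_i f(hbar*omega_i / (kB*T))  [J mol^-1 K^-1];
#   -T*S / 1000 gives kJ/mol.

.kB <- 1.380649e-23        # J K^-1
.hbar <- 1.054571817e-34   # J s
.N_A <- 6.02214076e23      # mol^-1
.amu_kg <- 1.66053906660e-27  # kg
.R_gas <- .kB * .N_A       # J mol^-1 K^-1

# Standard atomic weights for the elements that occur in protein heavy-atom
# and hydrogen records (IUPAC 2021 conventional values).
.atomic_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
  S = 32.06, P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38,
  MG = 24.305, CA = 40.078, MN = 54.938, CU = 63.546, "NA" = 22.990,
  K = 39.098, CL = 35.45
)

#' Atomic mass lookup
#'
#' Returns standard atomic weights (amu) for element symbols.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in amu.
#' @export
element_mass <- function(element) {
  key <- toupper(trimws(element))
  m <- .atomic_masses[key]
  if (anyNA(m)) {
    bad <- unique(key[is.na(m)])
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}
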