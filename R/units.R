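#' @useDynLib dann, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm median nlm optim quantile rnorm runif sd var
#' @importFrom utils head modifyList read.csv tail write.csv
NULL

# Global unit system: kcal/mol, Angstrom, fs, amu, Kelvin, degrees at the
# user surface (radians internally).  One internal unit system avoids silent
# eV/kcal mixing.

#' Physical constants used throughout the package
#'
#' All energies are kcal/mol, lengths Angstrom, times fs, masses amu.
#'
#' @format A named list:
#' \describe{
#'   \item{ev_to_kcal}{1 eV in kcal/mol (23.060548)}
#'   \item{kB}{Boltzmann constant, kcal/mol/K}
#'   \item{hbar}{reduced Planck constant, kcal/mol * fs}
#'   \item{acc}{acceleration conversion: (kcal/mol/A)/amu to A/fs^2}
#'   \item{kin}{kinetic energy conversion: amu*A^2/fs^2 to kcal/mol}
#' }
#' @export
dann_constants <- list(
  ev_to_kcal = 23.060548,
  kB = 0.0019872041,
  hbar = 15.178729,
  acc = 4.184e-4,
  kin = 1 / 4.184e-4
)

# atomic masses (amu) by atomic number, CIAAW standard weights
.atomic_masses <- c(
  1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948
)

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"
)

#' Atomic masses from atomic numbers
#' @param z integer vector of atomic numbers
#' @return numeric vector of masses in amu
#' @export
atomic_masses <- function(z) {
  stopifnot(all(z >= 1), all(z <= length(.atomic_masses)))
  .atomic_masses[z]
}

element_symbol <- function(z) .element_symbols[z]

symbol_to_z <- function(sym) {
  z <- match(sym, .element_symbols)
  if (anyNA(z)) stop("unknown element symbol: ", paste(sym[is.na(z)], collapse = ", "))
  z
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
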