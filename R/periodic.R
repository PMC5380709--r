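# Element data used throughout: masses of the most abundant isotope (amu)
# and single-bond covalent radii (Angstrom, Cordero et al. 2008 values).
# "X" is a unit-mass pseudo-atom used to wrap low-dimensional test surfaces
# as one-atom geometries.

.ATOMIC_MASS <- c(
  X  = 1.000000,
  H  = 1.007825,  He = 4.002603,
  Li = 7.016004,  Be = 9.012182,  B  = 11.009305, C  = 12.000000,
  N  = 14.003074, O  = 15.994915, F  = 18.998403, Ne = 19.992440,
  Na = 22.989770, Mg = 23.985042, Al = 26.981538, Si = 27.976927,
  P  = 30.973762, S  = 31.972071, Cl = 34.968853, Ar = 39.962383,
  K  = 38.963707, Ca = 39.962591, Fe = 55.934942, Zn = 63.929147,
  Se = 79.916522, Br = 78.918338, I  = 126.904468
)

.COVALENT_RADIUS <- c(
  X  = 0.32,
  H  = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B  = 0.84, C  = 0.76,
  N  = 0.71, O  = 0.66, F  = 0.57, Ne = 0.58,
  Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11,
  P  = 1.07, S  = 1.05, Cl = 1.02, Ar = 1.06,
  K  = 2.03, Ca = 1.76, Fe = 1.32, Zn = 1.22,
  Se = 1.20, Br = 1.20, I  = 1.39
)

.ATOMIC_NUMBER <- c(
  X  = 0L,
  H  = 1L,  He = 2L,
  Li = 3L,  Be = 4L,  B  = 5L,  C  = 6L,
  N  = 7L,  O  = 8L,  F  = 9L,  Ne = 10L,
  Na = 11L, Mg = 12L, Al = 13L, Si = 14L,
  P  = 15L, S  = 16L, Cl = 17L, Ar = 18L,
  K  = 19L, Ca = 20L, Fe = 26L, Zn = 30L,
  Se = 34L, Br = 35L, I  = 53L
)

#' Atomic mass of the most abundant isotope
#'
#' @param element character vector of element symbols.
#' @return numeric vector of masses in amu.
#' @export
atomic_mass <- function(element) {
  m <- .ATOMIC_MASS[element]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Single-bond covalent radius
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
covalent_radius <- function(element) {
  r <- .COVALENT_RADIUS[element]
  if (anyNA(r)) {
    stop("element(s) missing from covalent-radius table: ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

# symbol of the element one atomic number above (used by neutralization
# mutations that delete a hydrogen and promote its donor, e.g. N->O, O->F)
.next_element <- function(element) {
  z <- .ATOMIC_NUMBER[element]
  if (is.na(z)) stop("unknown element symbol: ", element)
  hit <- names(.ATOMIC_NUMBER)[match(z + 1L, .ATOMIC_NUMBER)]
  if (is.na(hit)) {
    stop("no defined promotion for donor element '", element, "'")
  }
  hit
}
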