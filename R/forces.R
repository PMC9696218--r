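#' Bjerrum length
#'
#' Separation at which two elementary charges interact with thermal energy
#' `kB T` in a dielectric medium: `lB = q^2 / (4 pi eps0 eps_r kB T)`.
#'
#' @param T Temperature in kelvin, positive.
#' @param eps_r Relative permittivity, positive; defaults to the linear
#'   dielectric law at `T`.
#' @return Bjerrum length in metres (about 0.65 nm in water at 298 K).
#' @export
#' @examples
#' bjerrum_length(298) * 1e9  # nm
bjerrum_length <- function(T, eps_r = relative_permittivity(T)) {
  if (any(!is.finite(T)) || any(T <= 0)) stop("`T` must be positive.", call. = FALSE)
  if (any(!is.finite(eps_r)) || any(eps_r <= 0)) stop("`eps_r` must be positive.", call. = FALSE)
  .const$q^2 / (4 * pi * .const$eps0 * eps_r * .const$kB * T)
}

# Debye length in metres from raw condition values.  Molar concentration is
# converted to a number density with Na * 1000 (mol/L -> particles/m^3).
.debye_length <- function(conc, Z, T, eps_r) {
  sqrt(.const$eps0 * eps_r * .const$kB * T /
         (conc * 1000 * .const$Na * .const$q^2 * Z^2))
}

#' Debye screening length of a medium
#'
#' `lambda_D = sqrt(eps0 eps_r kB T / (c Na q^2 Z^2))` with the molar
#' concentration `c` converted to particles per cubic metre (factor
#' `Na * 1000`).  The screening wavenumber is `kappa = 1 / lambda_D`.
#'
#' @param med A [medium()].
#' @return Debye length(s) in metres, one per concentration in `med`.
#' @export
#' @examples
#' debye_length(medium(0.1)) * 1e9  # ~1.4 nm under the counterion-only convention
debye_length <- function(med) {
  stopifnot(inherits(med, "dna_medium"))
  .debye_length(med$conc, med$Z, med$T, med$eps_r)
}

# Manning's condensation axial force divided by kB T, in 1/m.  This is the
# quantity that enters every persistence-length expression; keeping it as a
# helper avoids repeated kB T round trips.
.fele_over_kT <- function(conc, Z, T, eps_r, geom) {
  lB <- bjerrum_length(T, eps_r)
  lD <- .debye_length(conc, Z, T, eps_r)
  kb <- geom$b / lD
  if (any(kb <= 0)) stop("`conc` = 0 is unsupported (kappa b = 0).", call. = FALSE)
  xi <- lB / geom$b
  em <- exp(-kb)
  ((2 * Z * xi - 1) * kb * em / (1 - em) - 1 - log1p(-em)) / (Z^2 * lB)
}

#' Electrostatic axial support reaction force
#'
#' Manning's counterion-condensation expression for the compressive axial
#' force that electrostatic self-repulsion of the charged backbone exerts on
#' an end-constrained fragment:
#' `F_ele = kB T / (Z^2 lB) * [(2 Z xi - 1) kb e^-kb / (1 - e^-kb) - 1 - ln(1 - e^-kb)]`
#' with `xi = lB / b` the Manning charge-density parameter and
#' `kb = b / lambda_D`.  The bracket changes sign at very high salt, so the
#' force may be negative there; it grows logarithmically as `conc -> 0` and
#' tends to `-kB T / (Z^2 lB)` as `conc -> Inf`.
#'
#' @param med A [medium()]; vectorised over its concentrations.
#' @param geom A [dna_geometry()].
#' @return Force(s) in newtons (tens of pN at 0.1 M monovalent salt, 298 K).
#' @export
#' @examples
#' electrostatic_force(medium(0.1)) * 1e12  # pN
electrostatic_force <- function(med, geom = dna_geometry()) {
  stopifnot(inherits(med, "dna_medium"), inherits(geom, "dna_geometry"))
  .const$kB * med$T * .fele_over_kT(med$conc, med$Z, med$T, med$eps_r, geom)
}

#' Thermal-fluctuation axial support reaction force
#'
#' Axial reaction force contributed by thermal fluctuation of a fragment of
#' critical buckling length `lcb`: `F_tf = sqrt(E A kB T / lcb)`.  The
#' stretching modulus is eliminated through the worm-like-chain flexural
#' rigidity, `E I = kB T lp` with `I = A R^2 / 4`, giving
#' `E A = 4 kB T lp / R^2` and hence `F_tf = (2 kB T / R) sqrt(lp / lcb)`.
#'
#' @param lp Persistence length in metres, >= 0.
#' @param lcb Critical buckling length in metres, > 0.
#' @param geom A [dna_geometry()].
#' @param T Temperature in kelvin.
#' @return Force(s) in newtons, always >= 0; vectorised over `lp`/`lcb`.
#' @export
#' @examples
#' thermal_force(50e-9, 6e-9) * 1e12  # pN
thermal_force <- function(lp, lcb, geom = dna_geometry(), T = 298) {
  if (any(!is.finite(lp)) || any(lp < 0)) stop("`lp` must be >= 0.", call. = FALSE)
  if (any(!is.finite(lcb)) || any(lcb <= 0)) stop("`lcb` must be > 0.", call. = FALSE)
  2 * .const$kB * T / geom$R * sqrt(lp / lcb)
}
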