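#' Physical constants used throughout the package
#'
#' Returns the fixed set of physical constants the model is evaluated with:
#' Boltzmann constant `kB` (J/K), elementary charge `q` (C), vacuum
#' permittivity `eps0` (F/m) and Avogadro's number `Na` (1/mol).  All internal
#' computation is in SI units; nanometre/picoNewton conversions happen only at
#' user-facing table interfaces.
#'
#' @return A named list with elements `kB`, `q`, `eps0`, `Na`.
#' @export
#' @examples
#' phys_constants()$kB
phys_constants <- function() {
  list(kB = 1.38e-23, q = 1.6e-19, eps0 = 8.85e-12, Na = 6.022e23)
}

.const <- phys_constants()

#' DNA cross-section geometry
#'
#' The fragment is treated as a uniform circular elastic rod.  `R` is the
#' cross-section radius and `b` the axial spacing of the phosphate charges
#' along the double helix.  Cross-section area `A = pi R^2` and second moment
#' of area `I = pi R^4 / 4` are derived.
#'
#' @param R Cross-section radius in metres (default 1 nm).
#' @param b Charge spacing along the backbone in metres (default 0.17 nm).
#' @return An object of class `dna_geometry`: a list with `R`, `b`, `A`, `I`.
#' @export
#' @examples
#' geom <- dna_geometry()
#' geom$I  # pi/4 * (1 nm)^4
dna_geometry <- function(R = 1e-9, b = 0.17e-9) {
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("`R` must be a single positive number (metres).", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("`b` must be a single positive number (metres).", call. = FALSE)
  structure(
    list(R = R, b = b, A = pi * R^2, I = pi * R^4 / 4),
    class = "dna_geometry"
  )
}

#' Temperature-dependent relative permittivity of water
#'
#' Linear empirical law `eps_r = 87.74 - 0.4 (T - 293)`, valid between 278 K
#' and 313 K; temperatures outside that window trigger a warning but still
#' evaluate the linear formula.
#'
#' @param T Temperature(s) in kelvin; must be positive.
#' @return Relative permittivity (dimensionless), vectorised over `T`.
#' @export
#' @examples
#' relative_permittivity(298)  # 85.74
relative_permittivity <- function(T) {
  if (!is.numeric(T) || any(!is.finite(T)) || any(T <= 0))
    stop("`T` must be positive and finite (kelvin).", call. = FALSE)
  if (any(T < 278 | T > 313))
    warning("temperature outside the dielectric law's validity window [278, 313] K",
            call. = FALSE)
  87.74 - 0.4 * (T - 293)
}

#' Ionic/thermal environment of the DNA fragment
#'
#' Bundles the ionic condition and temperature from which every screening
#' quantity derives: counterion molar concentration `conc` (mol/L), unsigned
#' counterion valence `Z`, temperature `T` (K) and relative permittivity
#' `eps_r`.  `eps_r` defaults to the linear dielectric law
#' [relative_permittivity()] but can be overridden for sensitivity studies.
#' `conc` may be a vector so that one medium describes a concentration sweep
#' at fixed salt and temperature; `Z`, `T` and `eps_r` are scalars.
#'
#' @param conc Ionic concentration(s) in mol/L, strictly positive.
#' @param Z Unsigned counterion valence, integer >= 1 (1 for Na+, 2 for Mg2+).
#' @param T Temperature in kelvin.
#' @param eps_r Relative permittivity; `NULL` (default) uses the dielectric law.
#' @return An object of class `dna_medium`.
#' @export
#' @examples
#' medium(0.1)            # 0.1 M monovalent salt at 298 K
#' medium(0.05, Z = 2)    # divalent counterions
medium <- function(conc, Z = 1L, T = 298, eps_r = NULL) {
  if (!is.numeric(conc) || length(conc) < 1L || any(!is.finite(conc)) || any(conc <= 0))
    stop("`conc` must be positive and finite (mol/L).", call. = FALSE)
  if (!is.numeric(Z) || length(Z) != 1L || Z < 1 || Z != round(Z))
    stop("`Z` must be a single integer valence >= 1.", call. = FALSE)
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    stop("`T` must be a single positive temperature (kelvin).", call. = FALSE)
  if (is.null(eps_r)) {
    eps_r <- relative_permittivity(T)
  } else if (!is.numeric(eps_r) || length(eps_r) != 1L || eps_r <= 0) {
    stop("`eps_r` must be a single positive number.", call. = FALSE)
  }
  structure(
    list(conc = as.numeric(conc), Z = as.integer(Z), T = as.numeric(T),
         eps_r = as.numeric(eps_r)),
    class = "dna_medium"
  )
}

#' @export
print.dna_medium <- function(x, ...) {
  cat(sprintf("<dna_medium> Z = %d, T = %.1f K, eps_r = %.2f\n", x$Z, x$T, x$eps_r))
  cat("  conc (mol/L): ", paste(signif(x$conc, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.dna_geometry <- function(x, ...) {
  cat(sprintf("<dna_geometry> R = %.3g nm, b = %.3g nm\n", x$R * 1e9, x$b * 1e9))
  invisible(x)
}
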