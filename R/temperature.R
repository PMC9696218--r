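#' Empirical temperature dependence of persistence length (cyclization)
#'
#' Empirical law from cyclization measurements on short circularised DNA:
#' `lp(T) = (3.19 - 0.00414 T) x 10^-19 / (kB T)` nanometres, i.e. about
#' 47.6 nm at 298 K and strictly decreasing over the non-denaturing window
#' 278-313 K.
#'
#' @param T Temperature(s) in kelvin, preferably within 278-313 K.
#' @return Persistence length(s) in metres.
#' @export
#' @examples
#' geggier_lp(298) * 1e9  # ~47.6 nm
geggier_lp <- function(T) {
  if (any(!is.finite(T)) || any(T <= 0)) stop("`T` must be positive.", call. = FALSE)
  lp <- (3.19 - 0.00414 * T) * 1e-19 / (.const$kB * T) * 1e-9
  if (any(lp <= 0))
    stop("empirical law gives non-positive persistence length at this T.",
         call. = FALSE)
  lp
}

#' Linear model of critical buckling length versus temperature
#'
#' @param intercept_a Intercept in metres.
#' @param gradient_g Gradient in metres per kelvin.
#' @return An object of class `lcb_lin` with fields `intercept_a` and
#'   `gradient_g`; evaluate it with [lcb_at()].
#' @export
lcb_linear_model <- function(intercept_a, gradient_g) {
  stopifnot(is.numeric(intercept_a), is.numeric(gradient_g),
            length(intercept_a) == 1L, length(gradient_g) == 1L)
  structure(list(intercept_a = intercept_a, gradient_g = gradient_g),
            class = "lcb_lin")
}

#' @export
print.lcb_lin <- function(x, ...) {
  cat(sprintf("<lcb_lin> lcb(T) = (%.4g %+.4g T) nm\n",
              x$intercept_a * 1e9, x$gradient_g * 1e9))
  invisible(x)
}

#' Evaluate a linear buckling-length model
#'
#' @param model An `lcb_lin` model.
#' @param T Temperature(s) in kelvin.
#' @return Buckling length(s) in metres.
#' @export
lcb_at <- function(model, T) {
  stopifnot(inherits(model, "lcb_lin"))
  model$intercept_a + model$gradient_g * T
}

#' Fit a linear buckling-length-versus-temperature law
#'
#' Step one of the temperature-transfer procedure: for each temperature in
#' `T_grid`, the persistence length given by `lp_of_T` is inverted through
#' the buckling polynomial (at fixed `mu` and ionic condition, with the
#' dielectric constant re-evaluated at each temperature) to a critical
#' buckling length, and an ordinary least-squares line is fitted through the
#' `(T, lcb)` points.
#'
#' @param lp_of_T Function mapping temperature (K) to persistence length (m);
#'   defaults to [geggier_lp()].
#' @param mu Effective length factor (0.5 for the clamp-clamp cyclization
#'   geometry).
#' @param conc Ionic concentration in mol/L.
#' @param Z Counterion valence.
#' @param T_grid Temperature grid in kelvin (default 278-313 K in 1 K steps).
#' @param geom A [dna_geometry()].
#' @return An `lcb_lin` model.
#' @export
fit_lcb_vs_T <- function(lp_of_T = geggier_lp, mu = 0.5, conc, Z = 1L,
                         T_grid = seq(278, 313, by = 1), geom = dna_geometry()) {
  stopifnot(is.function(lp_of_T))
  lcb <- vapply(T_grid, function(Ti) {
    lp <- lp_of_T(Ti)
    out <- tryCatch(buckling_from_persistence(lp, mu, medium(conc, Z = Z, T = Ti), geom),
                    error = function(e)
                      stop(sprintf("no physical buckling length at T = %.1f K: %s",
                                   Ti, conditionMessage(e)), call. = FALSE))
    out
  }, numeric(1))
  if (any(lcb <= 0))
    stop(sprintf("non-physical buckling length at T = %.1f K.",
                 T_grid[which(lcb <= 0)[1]]), call. = FALSE)
  co <- stats::coef(stats::lm(lcb ~ T_grid))
  lcb_linear_model(unname(co[1]), unname(co[2]))
}

#' Transfer a temperature gradient to another constraint class
#'
#' Step two of the temperature-transfer procedure: assume the gradient of
#' buckling length with temperature obtained for one constraint class applies
#' to another, and anchor the line at that class's mean buckling length at
#' 298 K: `intercept = lcb_at_298 - gradient_g * 298`.
#'
#' @param lcb_at_298 Buckling length at 298 K in metres, > 0.
#' @param gradient_g Gradient in metres per kelvin (the reference value is
#'   -0.0359 nm/K).
#' @return An `lcb_lin` model passing exactly through `(298, lcb_at_298)`.
#' @export
#' @examples
#' transfer_gradient(5.95e-9, -0.0359e-9)  # intercept 16.65 nm
transfer_gradient <- function(lcb_at_298, gradient_g) {
  if (!is.numeric(lcb_at_298) || length(lcb_at_298) != 1L || lcb_at_298 <= 0)
    stop("`lcb_at_298` must be a single positive length (m).", call. = FALSE)
  lcb_linear_model(lcb_at_298 - gradient_g * 298, gradient_g)
}

#' Persistence length versus temperature for a constraint class
#'
#' Step three of the temperature-transfer procedure: evaluate the linear
#' buckling-length law at each temperature and map it to a persistence
#' length through the buckling model, re-evaluating the dielectric constant
#' (and hence the electrostatic force) at each temperature.
#'
#' @param model An `lcb_lin` model.
#' @param mu Effective length factor of the constraint class.
#' @param conc Ionic concentration in mol/L (default 0.1 M).
#' @param Z Counterion valence.
#' @param T_grid Temperature grid in kelvin.
#' @param geom A [dna_geometry()].
#' @return A tibble with columns `T_K`, `lcb_nm`, `lp_nm`.
#' @export
#' @examples
#' m <- transfer_gradient(5.95e-9, -0.0359e-9)
#' lp_vs_temperature(m, mu = 1.021)
lp_vs_temperature <- function(model, mu, conc = 0.1, Z = 1L,
                              T_grid = seq(278, 313, by = 1),
                              geom = dna_geometry()) {
  stopifnot(inherits(model, "lcb_lin"))
  lcb <- lcb_at(model, T_grid)
  if (any(lcb <= 0))
    stop(sprintf("linear model gives non-positive lcb at T = %.1f K.",
                 T_grid[which(lcb <= 0)[1]]), call. = FALSE)
  lp <- vapply(seq_along(T_grid), function(i) {
    persistence_from_buckling(mu, lcb[i], medium(conc, Z = Z, T = T_grid[i]), geom)
  }, numeric(1))
  tibble::tibble(T_K = T_grid, lcb_nm = lcb * 1e9, lp_nm = lp * 1e9)
}
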