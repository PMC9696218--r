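#' @title Persistence length from critical buckling length
#'
#' @description
#' The model's central map.  Substituting the electrostatic and
#' thermal-fluctuation forces into Euler's buckling relation and eliminating
#' the square root yields a polynomial constraint, quartic in the critical
#' buckling length `lcb` and quadratic in the persistence length `lp`
#' (writing `f = F_ele / (kB T)`, units 1/m):
#'
#' `f^2 lcb^4 - (4 lp / R^2) lcb^3 - (2 pi^2 lp / mu^2) f lcb^2 + pi^4 lp^2 / mu^4 = 0`
#'
#' `persistence_from_buckling()` solves it for `lp`, taking the root that
#' coincides with the explicit all-positive-terms expansion
#'
#' `lp = [2 mu^4 lcb^3 + 2 mu^3 lcb^{5/2} sqrt(mu^2 lcb + pi^2 R^2 f) + pi^2 R^2 mu^2 lcb^2 f] / (pi^4 R^2)`
#'
#' Two degenerate limits anchor the coefficient set: with `f = 0` and
#' `mu = 0.5` it reduces to the null-isomer law `lp = lcb^3 / (4 pi^4 R^2)`,
#' and with the thermal term dropped it reduces to
#' `lp = mu^2 lcb^2 f / pi^2`.
#'
#' @param mu Effective length factor, > 0.
#' @param lcb Critical buckling length in metres, > 0.
#' @param med A [medium()]; vectorised over its concentrations.
#' @param geom A [dna_geometry()].
#' @return Persistence length(s) in metres, one per concentration.
#' @seealso [buckling_from_persistence()], [decompose_persistence()]
#' @export
#' @examples
#' persistence_from_buckling(1.021, 5.95e-9, medium(0.1)) * 1e9  # ~68 nm
persistence_from_buckling <- function(mu, lcb, med, geom = dna_geometry()) {
  stopifnot(inherits(med, "dna_medium"), inherits(geom, "dna_geometry"))
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("`mu` must be > 0.", call. = FALSE)
  if (any(!is.finite(lcb)) || any(lcb <= 0)) stop("`lcb` must be > 0.", call. = FALSE)
  f <- .fele_over_kT(med$conc, med$Z, med$T, med$eps_r, geom)
  .lp_from_lcb(mu, lcb, f, geom)
}

# Larger root of the quadratic in lp; written with the explicit discriminant
# factorisation 16 lcb^5 / R^4 * (lcb + pi^2 R^2 f / mu^2) for stability.
.lp_from_lcb <- function(mu, lcb, f, geom) {
  R2 <- geom$R^2
  A <- pi^4 / mu^4
  B <- 4 * lcb^3 / R2 + 2 * pi^2 * f * lcb^2 / mu^2
  disc <- 16 * lcb^5 / R2^2 * (lcb + pi^2 * R2 * f / mu^2)
  if (any(disc < 0))
    stop("no positive real persistence length for these inputs ",
         "(electrostatic force too strongly negative).", call. = FALSE)
  lp <- (B + sqrt(disc)) / (2 * A)
  if (any(!is.finite(lp)) || any(lp <= 0))
    stop("no positive real persistence length for these inputs.", call. = FALSE)
  lp
}

#' Evaluate the buckling polynomial constraint
#'
#' Residual of the quartic/quadratic polynomial linking `lp` and `lcb`
#' (see [persistence_from_buckling()]), scaled by `pi^4 lp^2 / mu^4` so a
#' consistent pair gives a relative residual near machine precision.  Useful
#' for verifying that a solved pair actually lies on the model manifold.
#'
#' @inheritParams persistence_from_buckling
#' @param lp Persistence length in metres.
#' @return Dimensionless scaled residual(s).
#' @export
buckling_residual <- function(lp, mu, lcb, med, geom = dna_geometry()) {
  stopifnot(inherits(med, "dna_medium"), inherits(geom, "dna_geometry"))
  f <- .fele_over_kT(med$conc, med$Z, med$T, med$eps_r, geom)
  R2 <- geom$R^2
  val <- f^2 * lcb^4 - 4 * lp * lcb^3 / R2 -
    2 * pi^2 * lp * f * lcb^2 / mu^2 + pi^4 * lp^2 / mu^4
  val / (pi^4 * lp^2 / mu^4)
}

#' Critical buckling length from persistence length
#'
#' Inverts the polynomial constraint for `lcb` at fixed `lp`, `mu` and
#' medium.  All four roots of the quartic are found with the companion-matrix
#' solver ([polyroot()]); the physical branch is the positive real root that
#' round-trips through [persistence_from_buckling()] to the input `lp` within
#' 1e-6 relative (squaring during the derivation introduces one spurious
#' positive root, which this filter rejects).  With `F_ele = 0` the quartic
#' collapses to the closed-form cube-root inversion of the null-isomer law.
#'
#' @inheritParams persistence_from_buckling
#' @param lp Persistence length in metres, > 0; vectorised.
#' @return Critical buckling length(s) in metres.
#' @export
#' @examples
#' lcb <- buckling_from_persistence(47.57e-9, 0.5, medium(0.1))
#' persistence_from_buckling(0.5, lcb, medium(0.1))  # round-trips
buckling_from_persistence <- function(lp, mu, med, geom = dna_geometry()) {
  stopifnot(inherits(med, "dna_medium"), inherits(geom, "dna_geometry"))
  if (any(!is.finite(lp)) || any(lp <= 0)) stop("`lp` must be > 0.", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("`mu` must be a single positive number.", call. = FALSE)
  f <- .fele_over_kT(med$conc, med$Z, med$T, med$eps_r, geom)
  n <- max(length(lp), length(f))
  lp <- rep_len(lp, n); f <- rep_len(f, n)
  vapply(seq_len(n), function(i) .lcb_from_lp(lp[i], mu, f[i], geom), numeric(1))
}

.lcb_from_lp <- function(lp, mu, f, geom) {
  R2 <- geom$R^2
  if (f == 0) return((pi^4 * lp * R2 / (4 * mu^4))^(1 / 3))
  # coefficients in increasing powers of lcb, scaled to nm to condition the
  # companion matrix (1e9^k per power of length)
  s <- 1e9
  co <- c(pi^4 * (lp * s)^2 / mu^4,
          0,
          -2 * pi^2 * (lp * s) * (f / s) / mu^2,
          -4 * (lp * s) / (R2 * s^2),
          (f / s)^2)
  roots <- polyroot(co)
  re <- Re(roots[abs(Im(roots)) < 1e-6 * Mod(roots)])
  re <- sort(re[re > 0]) / s
  if (length(re) == 0L)
    stop(sprintf("no positive real buckling length for lp = %.4g m, mu = %.4g.",
                 lp, mu), call. = FALSE)
  for (r in re) {
    lp_back <- .lp_from_lcb(mu, r, f, geom)
    if (abs(lp_back - lp) <= 1e-6 * lp) return(r)
  }
  stop(sprintf(paste0("no branch-consistent buckling length for lp = %.4g m, ",
                      "mu = %.4g; real roots found (m): %s"),
               lp, mu, paste(signif(re, 6), collapse = ", ")), call. = FALSE)
}

#' Decompose a persistence-length prediction into its three additive terms
#'
#' Splits the explicit persistence-length expression into its three additive
#' contributions: the term only depending on constraint (TODC,
#' `2 mu^4 lcb^3 / (pi^4 R^2)`), the term weakly depending on environment
#' (TWDE, `2 mu^3 lcb^{5/2} sqrt(mu^2 lcb + pi^2 R^2 f) / (pi^4 R^2)` — the
#' electrostatic scale `f = F_ele / kB T` enters only under the square root,
#' so it varies mildly with salt), and the term strongly depending on
#' environment (TSDE, `mu^2 lcb^2 f / pi^2`, linear in `f`).  The three terms
#' sum exactly to [persistence_from_buckling()].
#'
#' @inheritParams persistence_from_buckling
#' @return A tibble with one row per concentration and columns `conc_M`,
#'   `todc_nm`, `twde_nm`, `tsde_nm`, `lp_nm`.
#' @export
#' @examples
#' decompose_persistence(1.021, 5.95e-9, medium(c(0.01, 0.1, 1)))
decompose_persistence <- function(mu, lcb, med, geom = dna_geometry()) {
  stopifnot(inherits(med, "dna_medium"), inherits(geom, "dna_geometry"))
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("`mu` must be > 0.", call. = FALSE)
  if (any(!is.finite(lcb)) || any(lcb <= 0)) stop("`lcb` must be > 0.", call. = FALSE)
  f <- .fele_over_kT(med$conc, med$Z, med$T, med$eps_r, geom)
  R2 <- geom$R^2
  arg <- mu^2 * lcb + pi^2 * R2 * f
  if (any(arg < 0))
    stop("no real decomposition: electrostatic force too strongly negative.",
         call. = FALSE)
  todc <- 2 * mu^4 * lcb^3 / (pi^4 * R2)
  twde <- 2 * mu^3 * lcb^2.5 * sqrt(arg) / (pi^4 * R2)
  tsde <- mu^2 * lcb^2 * f / pi^2
  tibble::tibble(
    conc_M = med$conc,
    todc_nm = todc * 1e9,
    twde_nm = rep_len(twde, length(med$conc)) * 1e9,
    tsde_nm = rep_len(tsde, length(med$conc)) * 1e9,
    lp_nm = (todc + twde + tsde) * 1e9
  )
}

#' Predict a persistence-length-versus-salt curve with an uncertainty band
#'
#' Evaluates the model over a concentration grid at the central effective
#' length factor `mu` and at `mu - sigma_mu` / `mu + sigma_mu`, holding `lcb`
#' fixed: the band propagates only the spread of the averaged effective
#' length factor, the spread of the averaged buckling length being excluded
#' to avoid counting the same statistical error twice.
#'
#' @inheritParams persistence_from_buckling
#' @param conc Concentration grid in mol/L (default: 40 log-spaced points on
#'   0.001-4 M).
#' @param Z Counterion valence.
#' @param T Temperature in kelvin.
#' @param sigma_mu Standard deviation of `mu`, >= 0 and < `mu`.
#' @return A tibble with columns `conc_M`, `lp_nm`, `lp_lo_nm`, `lp_hi_nm`.
#' @export
#' @examples
#' predict_lp_curve(1.021, 5.95e-9, sigma_mu = 0.250)
predict_lp_curve <- function(mu, lcb, conc = default_conc_grid(), Z = 1L,
                             T = 298, sigma_mu = 0, geom = dna_geometry()) {
  if (!is.numeric(sigma_mu) || length(sigma_mu) != 1L || sigma_mu < 0)
    stop("`sigma_mu` must be a single number >= 0.", call. = FALSE)
  if (mu - sigma_mu <= 0)
    stop("`mu - sigma_mu` must stay positive.", call. = FALSE)
  med <- medium(conc, Z = Z, T = T)
  lp <- persistence_from_buckling(mu, lcb, med, geom)
  if (sigma_mu == 0) {
    lo <- hi <- lp
  } else {
    a <- persistence_from_buckling(mu - sigma_mu, lcb, med, geom)
    b <- persistence_from_buckling(mu + sigma_mu, lcb, med, geom)
    lo <- pmin(a, b); hi <- pmax(a, b)
  }
  tibble::tibble(conc_M = conc, lp_nm = lp * 1e9,
                 lp_lo_nm = lo * 1e9, lp_hi_nm = hi * 1e9)
}

#' Default log-spaced concentration grid
#'
#' @param n Number of points.
#' @param from,to Grid limits in mol/L (default 0.001-4 M, the coverage of
#'   the salt-dependence analysis).
#' @return Numeric vector of concentrations in mol/L.
#' @export
default_conc_grid <- function(n = 40L, from = 0.001, to = 4) {
  exp(seq(log(from), log(to), length.out = n))
}
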