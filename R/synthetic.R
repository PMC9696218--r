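#' Generate a synthetic persistence-length-versus-salt dataset
#'
#' Evaluates the buckling model at the true parameters over a concentration
#' grid and multiplies each persistence length by lognormal noise with the
#' requested coefficient of variation (mean 1, so the noise is unbiased on
#' the natural scale).  Seed-deterministic; `noise_cv = 0` returns the exact
#' model curve.  This is the stand-in for the digitised literature curves
#' that the fitted parameters in [experiment_table()] summarise.
#'
#' @param mu_true,lcb_true True effective length factor and buckling length
#'   (m).
#' @param conc Concentration grid in mol/L (default: 12 log-spaced points on
#'   0.001-4 M).
#' @param Z Counterion valence.
#' @param T Temperature in kelvin.
#' @param noise_cv Coefficient of variation of the multiplicative noise,
#'   >= 0.
#' @param seed Integer seed.
#' @param constraint_class,label Metadata passed to [lp_dataset()].
#' @param geom A [dna_geometry()].
#' @return An [lp_dataset()].
#' @export
#' @examples
#' ds <- generate_lp_dataset(0.8, 7e-9, noise_cv = 0.05, seed = 1)
#' fit_dataset(ds)
generate_lp_dataset <- function(mu_true, lcb_true,
                                conc = default_conc_grid(12L), Z = 1L, T = 298,
                                noise_cv = 0.05, seed = 1L,
                                constraint_class = "suspended",
                                label = "synthetic", geom = dna_geometry()) {
  if (!is.numeric(noise_cv) || length(noise_cv) != 1L || noise_cv < 0)
    stop("`noise_cv` must be a single number >= 0.", call. = FALSE)
  med <- medium(conc, Z = Z, T = T)
  lp <- persistence_from_buckling(mu_true, lcb_true, med, geom)
  fac <- if (noise_cv == 0) rep(1, length(conc)) else {
    sdlog <- sqrt(log1p(noise_cv^2))
    withr::with_seed(seed, stats::rlnorm(length(conc), -sdlog^2 / 2, sdlog))
  }
  lp_dataset(tibble::tibble(concentration_M = conc, lp_nm = lp * fac * 1e9),
             T = T, Z = Z, constraint_class = constraint_class, label = label)
}
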