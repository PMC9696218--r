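#' Fitted buckling parameters across published experiments
#'
#' The package's reference table of ten published salt-dependence
#' experiments on double-stranded DNA, with the effective length factor,
#' critical buckling length and goodness of fit obtained by fitting the
#' buckling model to each experiment's persistence-length-versus-salt
#' curve.  Values are stored at the precision they are reported with; the
#' underlying digitised experimental curves are external literature data and
#' are not shipped.
#'
#' @return A tibble with columns `method`, `constraint_class`, `T_K`,
#'   `salt`, `Z`, `conc_min_M`, `conc_max_M`, `contour_bp`, `mu`, `lcb_nm`,
#'   `r2`.
#' @export
#' @examples
#' aggregate_class(subset(experiment_table(), constraint_class == "suspended"))
experiment_table <- function() {
  tibble::tribble(
    ~method,                    ~constraint_class, ~T_K, ~salt,      ~Z, ~conc_min_M, ~conc_max_M, ~contour_bp, ~mu,   ~lcb_nm, ~r2,
    "Rayleigh light scattering", "suspended",       293, "NaH2PO4",  1L, 0.005,       3,           39000L,      0.668, 9.16,    0.893,
    "Linear dichroism",          "suspended",       298, "NaCl",     1L, 0.002,       1,           39000L,      1.256, 4.18,    0.652,
    "Flow birefringence",        "suspended",       298, "NaCl",     1L, 0.002,       1,           39000L,      1.065, 5.14,    0.815,
    "Dynamic light scattering",  "suspended",       298, "NaCl",     1L, 0.005,       4,           6594L,       1.095, 5.31,    0.761,
    "Optical tweezers",          "fix_bead",        298, "NaCl",     1L, 0.00186,     0.586,       48500L,      0.635, 9.64,    0.511,
    "Tethered-particle method",  "fix_bead",        298, "NaCl",     1L, 0.015,       3.33,        2060L,       0.835, 6.52,    0.824,
    "Tethered-particle method",  "fix_bead",        298, "NaCl",     1L, 0.015,       3.33,        1201L,       0.686, 7.88,    0.911,
    "Tethered-particle method",  "fix_bead",        298, "MgCl2",    2L, 0.003,       0.104,       2060L,       0.736, 8.95,    0.614,
    "Tethered-particle method",  "fix_bead",        298, "MgCl2",    2L, 0.003,       0.104,       1201L,       0.700, 9.18,    0.624,
    "Electron microscopy",       "adsorbed",        298, "NaCl",     1L, 0.03,        0.5,         4800L,       0.489, 15.83,   0.404
  )
}

#' Class-averaged buckling parameters (reference values)
#'
#' The published class aggregates: mean and sample standard deviation of the
#' effective length factor and critical buckling length over the suspended
#' and fix-bead rows of [experiment_table()], at reported precision.
#' [aggregate_class()] reproduces every cell from the per-experiment values.
#'
#' @return A tibble with columns `constraint_class`, `mu_mean`, `mu_sd`,
#'   `lcb_mean_nm`, `lcb_sd_nm`.
#' @export
constraint_class_table <- function() {
  tibble::tribble(
    ~constraint_class, ~mu_mean, ~mu_sd, ~lcb_mean_nm, ~lcb_sd_nm,
    "suspended",       1.021,    0.250,  5.95,         2.20,
    "fix_bead",        0.718,    0.075,  8.43,         1.25
  )
}
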