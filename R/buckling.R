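#' Critical buckling length under a given axial load
#'
#' Euler's relation for an end-constrained column: the fragment of flexural
#' rigidity `EI` loaded axially by `P` first buckles at length
#' `lcb = (pi / mu) sqrt(EI / P)`, where `mu` is the effective length factor
#' of the end constraint (1 for hinge-hinge, 0.5 for clamp-clamp).
#' Equivalently `P = pi^2 EI / (mu lcb)^2`.
#'
#' @param P Axial compressive load in newtons, > 0.
#' @param EI Flexural rigidity in N m^2, > 0.
#' @param mu Effective length factor, > 0.
#' @return Critical buckling length in metres.
#' @export
#' @examples
#' critical_length_from_load(1, 1 / pi^2, mu = 1)  # 1
critical_length_from_load <- function(P, EI, mu) {
  if (any(!is.finite(P)) || any(P <= 0))
    stop("`P` must be > 0: no buckling under tension.", call. = FALSE)
  if (any(!is.finite(EI)) || any(EI <= 0)) stop("`EI` must be > 0.", call. = FALSE)
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("`mu` must be > 0.", call. = FALSE)
  (pi / mu) * sqrt(EI / P)
}

#' Critical buckling load of a fragment of given length
#'
#' Inverse of [critical_length_from_load()]: `P = pi^2 EI / (mu lcb)^2`.
#'
#' @param lcb Critical buckling length in metres, > 0.
#' @inheritParams critical_length_from_load
#' @return Load in newtons.
#' @export
critical_load <- function(lcb, EI, mu) {
  if (any(!is.finite(lcb)) || any(lcb <= 0)) stop("`lcb` must be > 0.", call. = FALSE)
  if (any(!is.finite(EI)) || any(EI <= 0)) stop("`EI` must be > 0.", call. = FALSE)
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("`mu` must be > 0.", call. = FALSE)
  pi^2 * EI / (mu * lcb)^2
}

# Dimensionless stiffness above which an end is treated as rigid.  Beyond
# this the general rows of the characteristic matrix lose precision, so the
# exact clamped/pinned limit rows are substituted instead.
.rigid_sentinel <- 1e8

# 4x4 boundary-condition matrix for the buckled shape
# y(s) = A sin(beta s) + B cos(beta s) + C s + D on s in [0, 1], with
# beta = L sqrt(P / EI).  Left end laterally pinned with rotational spring of
# dimensionless stiffness r1 = k_rot_left L / EI; right end carries a
# rotational spring r2 = k_rot_right L / EI and a lateral spring
# t = k_lat L^3 / EI.  Rigid springs (Inf or above the sentinel) use the
# exact limit rows y' = 0 / y = 0.
.char_matrix <- function(beta, r1, r2, t) {
  sb <- sin(beta); cb <- cos(beta)
  row1 <- c(0, 1, 0, 1)                                    # y(0) = 0
  row2 <- if (r1 >= .rigid_sentinel) c(beta, 0, 1, 0)      # y'(0) = 0
          else c(-r1 * beta, -beta^2, -r1, 0)              # EI y''(0) = k1 y'(0)
  row3 <- if (r2 >= .rigid_sentinel) c(beta * cb, -beta * sb, 1, 0)  # y'(1) = 0
          else c(-beta^2 * sb + r2 * beta * cb,            # EI y''(1) = -k2 y'(1)
                 -beta^2 * cb - r2 * beta * sb, r2, 0)
  row4 <- if (t >= .rigid_sentinel) c(sb, cb, 1, 1)        # y(1) = 0
          else c(t * sb, t * cb, beta^2 + t, t)            # shear + spring balance
  rbind(row1, row2, row3, row4)
}

.char_det <- function(beta, r1, r2, t) {
  m <- .char_matrix(beta, r1, r2, t)
  m <- m / pmax(apply(abs(m), 1, max), .Machine$double.xmin)
  det(m)
}

#' Effective length factor from elastic end constraints
#'
#' Solves the characteristic equation for the lowest buckling load of a
#' column with a rotational spring at each end, the left end pinned laterally
#' and the right end supported by a lateral spring, and returns the effective
#' length factor `mu = pi sqrt(EI / P1) / L` of that lowest mode.  Stiffness 0
#' means a free restraint and `Inf` a rigid one; the classical anchors are
#' hinge-hinge (`0, 0, Inf`) -> 1, clamp-clamp (`Inf, Inf, Inf`) -> 0.5,
#' clamp-hinge (`Inf, 0, Inf`) -> 0.6992 and clamp-free (`Inf, 0, 0`) -> 2.
#'
#' `mu` is continuous and non-increasing in each rotational stiffness.  The
#' lowest root of the characteristic determinant is located by sign-change
#' bracketing on a fine grid of the dimensionless load parameter followed by
#' bisection to 1e-12 relative.
#'
#' @param k_rot_left,k_rot_right Rotational spring stiffnesses in N m/rad,
#'   >= 0 (`Inf` = clamped).
#' @param k_lat Lateral spring stiffness at the right end in N/m, >= 0
#'   (`Inf` = pinned laterally).
#' @param EI Flexural rigidity in N m^2, > 0.
#' @param L Column length in metres, > 0.
#' @return Effective length factor `mu` (dimensionless, > 0).
#' @export
#' @examples
#' mu_from_springs(0, 0, Inf, 1, 1)       # 1 (hinge-hinge)
#' mu_from_springs(Inf, Inf, Inf, 1, 1)   # 0.5 (clamp-clamp)
mu_from_springs <- function(k_rot_left, k_rot_right, k_lat, EI, L) {
  if (!is.finite(EI) || EI <= 0) stop("`EI` must be > 0.", call. = FALSE)
  if (!is.finite(L) || L <= 0) stop("`L` must be > 0.", call. = FALSE)
  ks <- c(k_rot_left, k_rot_right, k_lat)
  if (any(is.na(ks)) || any(ks < 0))
    stop("spring stiffnesses must be >= 0 (Inf allowed for rigid).", call. = FALSE)
  r1 <- min(k_rot_left * L / EI, .rigid_sentinel)
  r2 <- min(k_rot_right * L / EI, .rigid_sentinel)
  t  <- min(k_lat * L^3 / EI, .rigid_sentinel)
  if (r1 == 0 && r2 == 0 && t == 0)
    stop("the column is a mechanism (all end restraints zero): no buckling load.",
         call. = FALSE)
  grid <- seq(1e-4, 2 * pi + 0.3, length.out = 8000L)
  v <- vapply(grid, .char_det, numeric(1), r1 = r1, r2 = r2, t = t)
  sgn <- which(v[-1] * v[-length(v)] < 0)
  if (length(sgn) == 0L)
    stop(sprintf(paste0("no buckling root bracketed for (r1 = %.3g, r2 = %.3g, ",
                        "t = %.3g); determinant has no sign change on the scan."),
                 r1, r2, t), call. = FALSE)
  i <- sgn[1L]
  beta <- stats::uniroot(.char_det, c(grid[i], grid[i + 1L]),
                         r1 = r1, r2 = r2, t = t, tol = 1e-12)$root
  pi / beta
}
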