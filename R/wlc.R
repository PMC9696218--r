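#' Mean-square end-to-end distance of a worm-like chain
#'
#' Closed-form WLC expectation
#' `<h^2> = 2 lp L [1 - lp (1 - exp(-L/lp)) / L]` for a chain of contour
#' length `L` and persistence length `lp`.  Strictly increasing in `lp` at
#' fixed `L`, which guarantees a unique inversion.
#'
#' @param lp Persistence length in metres, > 0; vectorised.
#' @param L Contour length in metres, > 0.
#' @return Mean-square end-to-end distance(s) in m^2.
#' @export
wlc_msee <- function(lp, L) {
  if (any(!is.finite(lp)) || any(lp <= 0)) stop("`lp` must be > 0.", call. = FALSE)
  if (any(!is.finite(L)) || any(L <= 0)) stop("`L` must be > 0.", call. = FALSE)
  2 * lp * L * (1 - lp * (1 - exp(-L / lp)) / L)
}

#' Persistence length from a mean-square end-to-end distance
#'
#' Inverts the WLC end-to-end relation (see [wlc_msee()]) for `lp` by
#' monotone one-dimensional root finding to 1e-10 relative tolerance.
#' `msee` must lie in `(0, L^2]`; values above `L^2` are unreachable for any
#' chain of contour length `L` and raise an error, while values at (or
#' numerically indistinguishable from) the rigid-rod limit `L^2` return
#' `Inf` as a divergence sentinel.
#'
#' @param msee Mean-square end-to-end distance in m^2.
#' @param L Contour length in metres.
#' @return Persistence length in metres (possibly `Inf` for a rigid rod).
#' @export
#' @examples
#' lp_from_msee(wlc_msee(50e-9, 17e-9), 17e-9)  # 50 nm
lp_from_msee <- function(msee, L) {
  if (!is.numeric(msee) || length(msee) != 1L || !is.finite(msee) || msee <= 0)
    stop("`msee` must be a single positive number (m^2).", call. = FALSE)
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("`L` must be a single positive length (m).", call. = FALSE)
  m <- msee / L^2                       # dimensionless target in (0, 1]
  if (m > 1 + 1e-12)
    stop("`msee` exceeds L^2: no chain of this contour length can reach it.",
         call. = FALSE)
  if (m >= 1 - 1e-12) return(Inf)
  g <- function(x) 2 * x * (1 - x * (1 - exp(-1 / x))) - m   # x = lp / L
  lo <- m / 2                            # msee <= 2 lp L  =>  x >= m/2
  hi <- max(1, 2 * lo)
  while (g(hi) < 0) {
    hi <- hi * 4
    if (hi > 1e15) return(Inf)
  }
  x <- stats::uniroot(g, c(lo * 0.999999, hi), tol = 1e-10 * hi)$root
  x * L
}

#' Sample a discrete worm-like-chain conformation ensemble
#'
#' Generates `n_chains` independent discrete WLC conformations of contour
#' length `L` with `n_segments` bonds of fixed length `L / n_segments`.
#' Successive bond directions deflect by a polar angle drawn from the WLC
#' Boltzmann density `p(cos theta) ~ exp(lambda cos theta)`, with `lambda`
#' chosen so that `<cos theta> = exp(-ds / lp)` (Langevin-function
#' inversion), and a uniform azimuth; the tangent autocorrelation therefore
#' decays exactly as `exp(-s / lp)` in expectation.  Sampling is
#' seed-deterministic.
#'
#' This sampler is the synthetic stand-in for conformation ensembles derived
#' from simulation trajectories (e.g. helical axes extracted from MD frames).
#'
#' @param lp Target persistence length in metres, > 0.
#' @param L Contour length in metres, > 0.
#' @param n_segments Number of bonds per chain, >= 10.
#' @param n_chains Number of conformations, >= 1.
#' @param seed Integer seed.
#' @return An object of class `chain_ensemble`: list with `conformations`
#'   (each an `(n_segments + 1) x 3` matrix of coordinates in metres) and
#'   attributes `lp`, `L`.
#' @export
#' @examples
#' ens <- sample_wlc(50e-9, 17e-9, n_segments = 50, n_chains = 10, seed = 1)
#' mean_square_end_to_end(ens)
sample_wlc <- function(lp, L, n_segments = 100L, n_chains = 100L, seed = 1L) {
  if (!is.finite(lp) || lp <= 0) stop("`lp` must be > 0.", call. = FALSE)
  if (!is.finite(L) || L <= 0) stop("`L` must be > 0.", call. = FALSE)
  if (n_segments < 10L) stop("`n_segments` must be >= 10.", call. = FALSE)
  if (n_chains < 1L) stop("`n_chains` must be >= 1.", call. = FALSE)
  ds <- L / n_segments
  g <- exp(-ds / lp)
  lambda <- .langevin_inverse(g)
  conf <- withr::with_seed(seed, {
    lapply(seq_len(n_chains), function(ch) {
      tang <- matrix(0, n_segments, 3L)
      tang[1L, ] <- c(0, 0, 1)
      if (n_segments > 1L) {
        u <- stats::runif(n_segments - 1L)
        phi <- stats::runif(n_segments - 1L, 0, 2 * pi)
        # inverse CDF of p(c) ~ exp(lambda c) on [-1, 1]
        ct <- if (is.finite(lambda) && lambda > 0)
          1 + log1p(u * expm1(-2 * lambda)) / lambda
        else 2 * u - 1                      # lambda -> 0: isotropic
        ct <- pmin(1, pmax(-1, ct))
        st <- sqrt(1 - ct^2)
        for (i in 2:n_segments) {
          tv <- tang[i - 1L, ]
          a <- if (abs(tv[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
          n1 <- a - sum(a * tv) * tv
          n1 <- n1 / sqrt(sum(n1^2))
          n2 <- c(tv[2L] * n1[3L] - tv[3L] * n1[2L],
                  tv[3L] * n1[1L] - tv[1L] * n1[3L],
                  tv[1L] * n1[2L] - tv[2L] * n1[1L])
          tang[i, ] <- ct[i - 1L] * tv +
            st[i - 1L] * (cos(phi[i - 1L]) * n1 + sin(phi[i - 1L]) * n2)
        }
      }
      rbind(c(0, 0, 0), apply(tang * ds, 2L, cumsum))
    })
  })
  structure(list(conformations = conf),
            class = "chain_ensemble", lp = lp, L = L)
}

# Inverse of the Langevin function coth(l) - 1/l = g on g in (0, 1).
.langevin_inverse <- function(g) {
  if (g <= 0) return(0)
  if (g >= 1) return(Inf)
  if (g > 1 - 1e-12) return(1 / (1 - g))
  stats::uniroot(function(l) 1 / tanh(l) - 1 / l - g,
                 c(1e-8, max(10, 2 / (1 - g))), tol = 1e-12)$root
}

#' @export
print.chain_ensemble <- function(x, ...) {
  n <- length(x$conformations)
  cat(sprintf("<chain_ensemble> %d conformation(s), %d points each\n",
              n, nrow(x$conformations[[1L]])))
  invisible(x)
}

#' Contour length of each conformation
#'
#' Measured along the polyline (the chain axis may flex, so the realised
#' contour length is the sum of segment lengths).
#'
#' @param ens A `chain_ensemble`.
#' @return Numeric vector of contour lengths in metres.
#' @export
contour_lengths <- function(ens) {
  stopifnot(inherits(ens, "chain_ensemble"))
  vapply(ens$conformations, function(m) {
    sum(sqrt(rowSums(diff(m)^2)))
  }, numeric(1))
}

#' Mean-square end-to-end distance of an ensemble
#'
#' Average over conformations of the squared distance between the first and
#' last axis points.  For trajectory-ordered ensembles the first `burn_in`
#' conformations (the unequilibrated frames) can be dropped.
#'
#' @param ens A `chain_ensemble`.
#' @param burn_in Number of leading conformations to discard (default 0).
#' @return Mean-square end-to-end distance in m^2.
#' @export
mean_square_end_to_end <- function(ens, burn_in = 0L) {
  stopifnot(inherits(ens, "chain_ensemble"))
  conf <- ens$conformations
  if (burn_in > 0L) conf <- conf[-seq_len(burn_in)]
  if (length(conf) == 0L)
    stop("no conformations left after burn-in.", call. = FALSE)
  mean(vapply(conf, function(m) {
    d <- m[nrow(m), ] - m[1L, ]
    sum(d^2)
  }, numeric(1)))
}

#' Estimate persistence length from a conformation ensemble
#'
#' End-to-end estimator: computes the (ensemble or per-conformation)
#' mean-square end-to-end distance and inverts the WLC relation at the mean
#' contour length.  `method = "ensemble"` (default) inverts the ensemble
#' average once; `method = "per_frame"` inverts each conformation separately
#' and averages the finite results.
#'
#' @param ens A `chain_ensemble`.
#' @param method `"ensemble"` or `"per_frame"`.
#' @param burn_in Leading conformations to discard.
#' @return A tibble with columns `lp_nm`, `msee_nm2`, `L_nm`,
#'   `n_conformations`, `method`.
#' @export
#' @examples
#' ens <- sample_wlc(50e-9, 17e-9, n_segments = 50, n_chains = 200, seed = 1)
#' estimate_lp(ens)
estimate_lp <- function(ens, method = c("ensemble", "per_frame"), burn_in = 0L) {
  stopifnot(inherits(ens, "chain_ensemble"))
  method <- match.arg(method)
  conf <- ens$conformations
  if (burn_in > 0L) conf <- conf[-seq_len(burn_in)]
  if (length(conf) == 0L) stop("no conformations left after burn-in.", call. = FALSE)
  sub <- structure(list(conformations = conf), class = "chain_ensemble")
  L <- mean(contour_lengths(sub))
  msee <- mean_square_end_to_end(sub)
  lp <- if (method == "ensemble") {
    lp_from_msee(msee, L)
  } else {
    per <- vapply(conf, function(m) {
      d <- m[nrow(m), ] - m[1L, ]
      lp_from_msee(sum(d^2), L)
    }, numeric(1))
    mean(per[is.finite(per)])
  }
  tibble::tibble(lp_nm = lp * 1e9, msee_nm2 = msee * 1e18, L_nm = L * 1e9,
                 n_conformations = length(conf), method = method)
}
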