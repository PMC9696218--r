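#' Construct a persistence-length-versus-salt dataset
#'
#' Validates and tags a table of `(concentration, persistence length)`
#' records with its experimental metadata.  At least 3 records are required,
#' concentrations must be strictly positive and unique, and persistence
#' lengths positive.
#'
#' @param data A data frame with columns `concentration_M` and `lp_nm` (or
#'   `lp_m`, converted on input).
#' @param T Temperature in kelvin.
#' @param Z Counterion valence.
#' @param constraint_class One of `"suspended"`, `"fix_bead"`, `"adsorbed"`.
#' @param label Free-text label for the dataset.
#' @return A tibble of class `lp_dataset` with columns `concentration_M`,
#'   `lp_nm` and metadata attributes `T`, `Z`, `constraint_class`, `label`.
#' @export
lp_dataset <- function(data, T = 298, Z = 1L,
                       constraint_class = c("suspended", "fix_bead", "adsorbed"),
                       label = "") {
  constraint_class <- match.arg(constraint_class)
  data <- tibble::as_tibble(data)
  if (!("lp_nm" %in% names(data)) && "lp_m" %in% names(data))
    data$lp_nm <- data$lp_m * 1e9
  if (!all(c("concentration_M", "lp_nm") %in% names(data)))
    stop("`data` needs columns `concentration_M` and `lp_nm` (or `lp_m`).",
         call. = FALSE)
  data <- data[c("concentration_M", "lp_nm")]
  if (nrow(data) < 3L) stop("need at least 3 records.", call. = FALSE)
  if (any(!is.finite(data$concentration_M)) || any(data$concentration_M <= 0))
    stop("concentrations must be positive and finite.", call. = FALSE)
  if (anyDuplicated(data$concentration_M))
    stop("concentrations must be unique.", call. = FALSE)
  if (any(!is.finite(data$lp_nm)) || any(data$lp_nm <= 0))
    stop("persistence lengths must be positive and finite.", call. = FALSE)
  structure(data,
            class = c("lp_dataset", class(data)),
            T = as.numeric(T), Z = as.integer(Z),
            constraint_class = constraint_class, label = label)
}

#' Coefficient of determination of a fit
#'
#' `r2 = 1 - SSR / TSS` with `SSR = sum((obs - pred)^2)` and
#' `TSS = sum((obs - mean(obs))^2)`.  A constant observation vector has
#' `TSS = 0`; `r2` is then reported as `NA` rather than raising a division
#' error.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return A list with elements `r2`, `ssr`, `tss`.
#' @export
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 4))$r2  # 0.5
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    stop("`observed` and `predicted` must have equal length >= 2.", call. = FALSE)
  ssr <- sum((observed - predicted)^2)
  tss <- sum((observed - mean(observed))^2)
  list(r2 = if (tss == 0) NA_real_ else 1 - ssr / tss, ssr = ssr, tss = tss)
}

#' Fit effective length factor and buckling length to a salt-dependence curve
#'
#' Bounded nonlinear least squares of the buckling model against an
#' [lp_dataset()]: minimises the unweighted sum of squared residuals of the
#' predicted versus observed persistence lengths (in nm) over
#' `(mu, lcb)`.  Because the SSR surface is a curved, shallow valley (both
#' parameters inflate the prediction together), the optimiser is restarted
#' from `n_starts` Latin-hypercube points spanning the bounds, drawn
#' deterministically from `seed`, and the best start is polished; the whole
#' fit is seed-deterministic.
#'
#' @param data An [lp_dataset()].
#' @param geom A [dna_geometry()].
#' @param bounds List with elements `mu` and `lcb_nm`, each `c(lower, upper)`.
#'   Defaults bracket the range of fitted values reported across published
#'   experiments (`mu` 0.3-2.5, `lcb` 1-30 nm).
#' @param n_starts Number of multi-starts (>= 1).
#' @param seed Integer seed for the start design.
#' @return An object of class `lp_fit`: list with `mu_hat`, `lcb_hat` (m),
#'   `r2`, `ssr`, `tss` (nm^2 scale), `residuals` (nm), `converged`, the
#'   data and the fit settings.
#' @seealso [tidy.lp_fit()], [glance.lp_fit()], [augment.lp_fit()],
#'   [autoplot.lp_fit()].
#' @export
fit_dataset <- function(data, geom = dna_geometry(),
                        bounds = list(mu = c(0.3, 2.5), lcb_nm = c(1, 30)),
                        n_starts = 8L, seed = 1L) {
  if (!inherits(data, "lp_dataset"))
    stop("`data` must be an `lp_dataset` (see lp_dataset()).", call. = FALSE)
  if (n_starts < 1L) stop("`n_starts` must be >= 1.", call. = FALSE)
  med <- medium(data$concentration_M, Z = attr(data, "Z"), T = attr(data, "T"))
  f <- .fele_over_kT(med$conc, med$Z, med$T, med$eps_r, geom)
  obs <- data$lp_nm
  ssr_fun <- function(p) {
    lp <- .lp_from_lcb(p[1], p[2] * 1e-9, f, geom) * 1e9
    sum((lp - obs)^2)
  }
  lower <- c(bounds$mu[1], bounds$lcb_nm[1])
  upper <- c(bounds$mu[2], bounds$lcb_nm[2])
  starts <- withr::with_seed(seed, lhs::randomLHS(n_starts, 2L))
  starts <- sweep(sweep(starts, 2L, upper - lower, "*"), 2L, lower, "+")
  best <- NULL
  any_ok <- FALSE
  msgs <- character(0)
  for (i in seq_len(n_starts)) {
    o <- tryCatch(
      stats::optim(starts[i, ], ssr_fun, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500L)),
      error = function(e) e)
    if (inherits(o, "error")) { msgs <- c(msgs, conditionMessage(o)); next }
    any_ok <- any_ok || o$convergence == 0L
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    out <- list(mu_hat = NA_real_, lcb_hat = NA_real_, r2 = NA_real_,
                ssr = NA_real_, tss = NA_real_, residuals = rep(NA_real_, length(obs)),
                converged = FALSE, diagnostics = msgs, data = data,
                bounds = bounds, n_starts = n_starts, seed = seed, geom = geom)
    return(structure(out, class = "lp_fit"))
  }
  # polish the winning start: tight L-BFGS-B, then a simplex refine (the
  # valley floor is too flat for gradient steps alone)
  o <- stats::optim(best$par, ssr_fun, method = "L-BFGS-B",
                    lower = lower, upper = upper,
                    control = list(factr = 10, maxit = 1000L))
  if (o$value <= best$value) best <- o
  pen_fun <- function(p) {
    if (any(p < lower) || any(p > upper)) return(best$value * 10 + 1)
    ssr_fun(p)
  }
  o <- stats::optim(best$par, pen_fun, method = "Nelder-Mead",
                    control = list(reltol = 1e-15, maxit = 2000L))
  if (o$value <= best$value) { best$par <- o$par; best$value <- o$value }
  pred <- .lp_from_lcb(best$par[1], best$par[2] * 1e-9, f, geom) * 1e9
  gof <- goodness_of_fit(obs, pred)
  structure(
    list(mu_hat = unname(best$par[1]), lcb_hat = unname(best$par[2]) * 1e-9,
         r2 = gof$r2, ssr = gof$ssr, tss = gof$tss,
         residuals = obs - pred, converged = any_ok, diagnostics = msgs,
         data = data, bounds = bounds, n_starts = n_starts, seed = seed,
         geom = geom),
    class = "lp_fit"
  )
}

#' @export
print.lp_fit <- function(x, ...) {
  cat("<lp_fit> buckling-model fit\n")
  if (nzchar(attr(x$data, "label"))) cat("  dataset:", attr(x$data, "label"), "\n")
  cat(sprintf("  mu = %.4g, lcb = %.4g nm, r2 = %s, converged = %s\n",
              x$mu_hat, x$lcb_hat * 1e9,
              ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2)), x$converged))
  invisible(x)
}

#' Tidy a buckling-model fit
#'
#' @param x An `lp_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`mu`, `lcb_nm`).
#' @exportS3Method generics::tidy
#' @export
tidy.lp_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "lcb_nm"),
                 estimate = c(x$mu_hat, x$lcb_hat * 1e9))
}

#' One-row summary of a buckling-model fit
#'
#' @param x An `lp_fit`.
#' @param ... Unused.
#' @return A tibble with `r.squared`, `ssr`, `tss`, `nobs`, `converged`.
#' @exportS3Method generics::glance
#' @export
glance.lp_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, ssr = x$ssr, tss = x$tss,
                 nobs = nrow(x$data), converged = x$converged)
}

#' Observation-level results of a buckling-model fit
#'
#' @param x An `lp_fit`.
#' @param ... Unused.
#' @return The dataset tibble plus `.fitted` and `.resid` columns (nm).
#' @exportS3Method generics::augment
#' @export
augment.lp_fit <- function(x, ...) {
  out <- tibble::as_tibble(x$data)
  out$.fitted <- out$lp_nm - x$residuals
  out$.resid <- x$residuals
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Aggregate fitted parameters over a constraint class
#'
#' Arithmetic mean and sample (n-1 denominator) standard deviation of the
#' fitted effective length factors and critical buckling lengths across the
#' experiments of one constraint class.
#'
#' @param fits Either a list of `lp_fit` objects or a data frame with
#'   columns `mu` and `lcb_nm` (e.g. a filtered [experiment_table()]).
#' @return A tibble with columns `n`, `mu_mean`, `mu_sd`, `lcb_mean_nm`,
#'   `lcb_sd_nm`.
#' @export
#' @examples
#' tab <- experiment_table()
#' aggregate_class(tab[tab$constraint_class == "suspended", ])
aggregate_class <- function(fits) {
  if (is.data.frame(fits)) {
    if (!all(c("mu", "lcb_nm") %in% names(fits)))
      stop("data frame input needs columns `mu` and `lcb_nm`.", call. = FALSE)
    mu <- fits$mu; lcb_nm <- fits$lcb_nm
  } else if (is.list(fits) && all(vapply(fits, inherits, logical(1), "lp_fit"))) {
    mu <- vapply(fits, `[[`, numeric(1), "mu_hat")
    lcb_nm <- vapply(fits, `[[`, numeric(1), "lcb_hat") * 1e9
  } else {
    stop("`fits` must be a list of lp_fit objects or a data frame.", call. = FALSE)
  }
  if (length(mu) < 2L) stop("need at least 2 fits to aggregate.", call. = FALSE)
  tibble::tibble(n = length(mu),
                 mu_mean = mean(mu), mu_sd = stats::sd(mu),
                 lcb_mean_nm = mean(lcb_nm), lcb_sd_nm = stats::sd(lcb_nm))
}
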