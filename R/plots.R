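#' Plot a fitted salt-dependence curve over its data
#'
#' Observed persistence lengths and the fitted model curve on a log
#' concentration axis.
#'
#' @param object An `lp_fit`.
#' @param n_grid Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.lp_fit <- function(object, n_grid = 120L, ...) {
  d <- tibble::as_tibble(object$data)
  grid <- default_conc_grid(n_grid, min(d$concentration_M), max(d$concentration_M))
  curve <- predict_lp_curve(object$mu_hat, object$lcb_hat, conc = grid,
                            Z = attr(object$data, "Z"), T = attr(object$data, "T"),
                            geom = object$geom)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration_M, y = .data$lp_nm)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$conc_M, y = .data$lp_nm),
                       colour = "#2166ac") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ionic concentration (mol/L)",
                  y = "persistence length (nm)",
                  title = sprintf("mu = %.3f, lcb = %.2f nm, r2 = %.3f",
                                  object$mu_hat, object$lcb_hat * 1e9,
                                  ifelse(is.na(object$r2), NaN, object$r2)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a predicted persistence-length curve with its uncertainty band
#'
#' @param curve A tibble from [predict_lp_curve()].
#' @return A ggplot object.
#' @export
plot_lp_curve <- function(curve) {
  stopifnot(all(c("conc_M", "lp_nm", "lp_lo_nm", "lp_hi_nm") %in% names(curve)))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$conc_M, y = .data$lp_nm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lp_lo_nm, ymax = .data$lp_hi_nm),
                         fill = "#92c5de", alpha = 0.5) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ionic concentration (mol/L)",
                  y = "persistence length (nm)")
}

#' Plot the three-term decomposition of predicted persistence length
#'
#' Stacked contributions of the constraint-only term and the weakly and
#' strongly environment-coupled terms across salt concentration.
#'
#' @param dec A tibble from [decompose_persistence()].
#' @return A ggplot object.
#' @export
plot_decomposition <- function(dec) {
  stopifnot(all(c("conc_M", "todc_nm", "twde_nm", "tsde_nm") %in% names(dec)))
  long <- tidyr::pivot_longer(dec, c("todc_nm", "twde_nm", "tsde_nm"),
                              names_to = "term", values_to = "nm")
  long$term <- factor(long$term, levels = c("tsde_nm", "twde_nm", "todc_nm"),
                      labels = c("TSDE", "TWDE", "TODC"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$conc_M, y = .data$nm,
                                     fill = .data$term)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ionic concentration (mol/L)",
                  y = "contribution to persistence length (nm)", fill = NULL)
}

#' @importFrom rlang .data
NULL
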