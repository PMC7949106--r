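#' Plot titration curves
#'
#' Protonation probability against pH, one line per site, with the
#' split-half discrepancy as an error bar.
#'
#' @param object A `titration_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.titration_fit <- function(object, ...) {
  d <- object$result
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pH, y = .data$p,
                                  colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(.data$p - .data$se, 0),
                                          ymax = pmin(.data$p + .data$se, 1)),
                             size = 0.2) +
    ggplot2::labs(y = "protonation probability",
                  title = "Monte Carlo titration") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot per-window free energies of an alchemical run
#'
#' Cumulative free energy along the lambda path for each environment and
#' direction; converged legs retrace each other with opposite sign.
#'
#' @param object A `fep_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fep_result <- function(object, ...) {
  d <- dplyr::mutate(
    dplyr::group_by(object$windows, .data$env, .data$direction),
    cumulative = cumsum(.data$dg))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lambda_to, y = .data$cumulative,
                                  colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::facet_wrap(~env) +
    ggplot2::labs(x = expression(lambda), y = "cumulative dG (kcal/mol)",
                  title = sprintf("%s -> %s alchemical transformation",
                                  object$ion_a, object$ion_b)) +
    ggplot2::theme_minimal()
}

#' Plot fitted DEER distance distributions
#'
#' `P(r)` per condition with its 2-sigma confidence band.
#'
#' @param object A `deer_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.deer_fit <- function(object, ...) {
  d <- purrr::imap_dfr(object$distributions, function(dist, cond) {
    out <- as_tibble(dist)
    out$condition <- cond
    out
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, colour = .data$condition,
                                  fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p)) +
    ggplot2::labs(x = "r (nm)", y = "P(r) (1/nm)",
                  title = "DEER distance distributions (band: 2 sigma)") +
    ggplot2::theme_minimal()
}

#' Plot observed and fitted DEER time traces
#'
#' @param fit A `deer_fit`.
#' @return A ggplot.
#' @export
plot_deer_traces <- function(fit) {
  stopifnot(inherits(fit, "deer_fit"))
  ggplot2::ggplot(fit$fitted, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.3,
                        alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "time (us)", y = "normalized echo amplitude") +
    ggplot2::theme_minimal()
}

#' Plot a distance probability distribution
#'
#' @param object A `distance_histogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.distance_histogram <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_col(width = attr(object, "bin_width"), fill = "steelblue") +
    ggplot2::labs(x = "distance (A)", y = "probability density (1/A)") +
    ggplot2::theme_minimal()
}

#' Plot a distance time series
#'
#' @param object A `distance_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.distance_series <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$distance)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ns)", y = "distance (A)",
                  title = attr(object, "pair")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
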