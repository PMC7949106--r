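#' Tidy a Monte Carlo titration fit
#'
#' @param x A `titration_fit`.
#' @param ... Unused.
#' @return One row per (site, pH): protonation probability, binomial
#'   standard error, split-half occupancies and their discrepancy.
#' @export
tidy.titration_fit <- function(x, ...) x$result

#' @rdname tidy.titration_fit
#' @return For `glance()`: one row per pH with sampler diagnostics plus the
#'   worst split-half discrepancy.
#' @export
glance.titration_fit <- function(x, ...) {
  worst <- dplyr::summarise(dplyr::group_by(x$result, .data$pH),
                            max_split_half = max(.data$split_half),
                            .groups = "drop")
  out <- dplyr::left_join(x$diagnostics, worst, by = "pH")
  out$seed <- x$seed
  out$ion_bound <- x$ion_bound
  out
}

#' Tidy an alchemical free-energy result
#'
#' @param x A `fep_result`.
#' @param ... Unused.
#' @return Per-window free energies: environment, direction, lambda
#'   interval, window free energy, acceptance.
#' @export
tidy.fep_result <- function(x, ...) x$windows

#' @rdname tidy.fep_result
#' @return For `glance()`: one row with ddG, per-leg means and hysteresis,
#'   fold preference and the deformation statistics (NA when ligands are
#'   fixed).
#' @export
glance.fep_result <- function(x, ...) {
  site <- x$legs[x$legs$env == "site", ]
  bulk <- x$legs[x$legs$env == "bulk", ]
  tibble(
    ion_a = x$ion_a, ion_b = x$ion_b, restrained = x$restrained,
    ddg = x$ddg,
    dg_site = site$dg_mean, dg_bulk = bulk$dg_mean,
    hysteresis_site = site$hysteresis, hysteresis_bulk = bulk$hysteresis,
    fold_preference = x$fold_preference,
    dD = if (is.null(x$geometry)) NA_real_ else x$geometry$dD,
    ddD = if (is.null(x$geometry)) NA_real_ else x$geometry$ddD,
    n_warnings = length(x$warnings), seed = x$seed
  )
}

#' Tidy a DEER mixture fit
#'
#' @param x A `deer_fit`.
#' @param ... Unused.
#' @return One row per (condition, component): mean, width, weight, plus
#'   the condition's modulation depth and background rate.
#' @export
tidy.deer_fit <- function(x, ...) {
  purrr::imap_dfr(x$models, function(m, cond) {
    out <- m$components
    out$condition <- cond
    out$depth <- m$depth
    out$bg_k <- m$bg_k
    out[, c("condition", "mean", "width", "weight", "depth", "bg_k")]
  })
}

#' @rdname tidy.deer_fit
#' @return For `glance()`: one row with the selected component count and
#'   the selection table's best score.
#' @export
glance.deer_fit <- function(x, ...) {
  sel <- x$selection[x$selection$k == x$selected_k, ]
  tibble(
    n_conditions = length(x$models), selected_k = x$selected_k,
    rss = sel$rss, bic = sel$bic, converged = sel$converged, seed = x$seed
  )
}

#' Tidy a coordination site
#'
#' @param x A `coord_site`.
#' @param ... Unused.
#' @return The contact tibble.
#' @export
tidy.coord_site <- function(x, ...) x$contacts

#' Tidy a valence report
#'
#' @param x A `valence_report`.
#' @param ... Unused.
#' @return The report as a plain tibble.
#' @export
tidy.valence_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "valence_report")
  attr(out, "best_match") <- NULL
  attr(out, "n_contacts") <- NULL
  out
}
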