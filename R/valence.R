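#' Empirical bond-valence parameters
#'
#' Built-in (R_o, N) pairs for the bond-valence metric, one row per ion,
#' together with the ion's formal charge. The values are the empirical
#' parameters commonly used to score alkali and alkaline-earth sites in
#' protein structures: Na+ (R_o 1.6 A, N 4.29), K+ (2.276, 9.1),
#' Ca2+ (1.909, 5.4).
#'
#' @param ions Subset of ions to return (default all).
#' @return A tibble with columns `ion`, `charge`, `r0`, `n`.
#' @examples
#' valence_params()
#' @export
valence_params <- function(ions = c("Na+", "K+", "Ca2+")) {
  tab <- tibble(
    ion = c("Na+", "K+", "Ca2+"),
    charge = c(1, 1, 2),
    r0 = c(1.6, 2.276, 1.909),
    n = c(4.29, 9.1, 5.4)
  )
  missing <- setdiff(ions, tab$ion)
  if (length(missing)) {
    abort(paste0("no built-in valence parameters for: ",
                 paste(missing, collapse = ", "),
                 "; pass a custom params tibble instead"))
  }
  tab[match(ions, tab$ion), ]
}

#' Bond valence of a set of contact distances
#'
#' The workhorse sum `sum_i (R_i / R_o)^(-N)` over ligand contact distances
#' `R_i` (Angstrom). The value approximates the formal charge of the ion
#' whose parameters are used, when the site geometry matches sites observed
#' for that ion.
#'
#' @param distances Numeric vector of contact distances, Angstrom; all > 0.
#' @param r0,n Empirical parameters for one ion (see [valence_params()]).
#' @return The dimensionless valence (0 for an empty distance vector).
#' @examples
#' bond_valence(rep(2.4, 5), r0 = 1.6, n = 4.29)
#' @export
bond_valence <- function(distances, r0, n) {
  stopifnot(is.numeric(distances), length(r0) == 1L, length(n) == 1L,
            r0 > 0, n > 0)
  if (length(distances) == 0L) return(0)
  if (any(!is.finite(distances)) || any(distances <= 0)) {
    abort("all contact distances must be finite and > 0")
  }
  sum((distances / r0)^(-n))
}

#' Bond valence of a coordination site
#'
#' @param site A `coord_site` from [extract_site()], or a numeric vector of
#'   contact distances.
#' @param ion Ion label looked up in `params`.
#' @param params Parameter table, as from [valence_params()].
#' @return The dimensionless valence for that ion.
#' @examples
#' s <- gen_coordination_site(distance = 2.4, seed = 1)
#' site <- extract_site(s$structure, center = s$truth$center_serial)
#' compute_valence(site, "Na+")
#' @export
compute_valence <- function(site, ion = "Na+", params = valence_params()) {
  d <- site_distances(site)
  row <- params[params$ion == ion, , drop = FALSE]
  if (nrow(row) != 1L) abort(paste0("ion '", ion, "' not found in params"))
  bond_valence(d, row$r0, row$n)
}

site_distances <- function(site) {
  if (inherits(site, "coord_site")) site$contacts$distance else as.numeric(site)
}

#' Rank candidate ions for a coordination site
#'
#' Computes the bond valence of the site under each ion's empirical
#' parameters and identifies the best match: the ion whose formal charge is
#' closest to its computed valence. Ties are broken by the smaller valence
#' deviation and then alphabetically by ion label. An empty site yields all
#' valences 0 and no best match.
#'
#' @inheritParams compute_valence
#' @param digits Decimal places used for the `valence_rounded` column
#'   (printed comparisons use 1 decimal; full precision is retained in
#'   `valence`).
#' @return A `valence_report`: a tibble with columns `ion`, `charge`,
#'   `valence`, `valence_rounded`, `deviation` (|valence - charge|) and
#'   `best_match` (logical), plus attributes `best_match` (ion label or NA)
#'   and `n_contacts`.
#' @examples
#' s <- gen_coordination_site(distance = 2.4, seed = 1)
#' site <- extract_site(s$structure, center = s$truth$center_serial)
#' rank_ions(site)
#' @export
rank_ions <- function(site, params = valence_params(), digits = 1) {
  stopifnot(nrow(params) >= 1L)
  d <- site_distances(site)
  rep <- params
  rep$valence <- vapply(seq_len(nrow(params)), function(i) {
    bond_valence(d, params$r0[i], params$n[i])
  }, numeric(1))
  rep$valence_rounded <- round(rep$valence, digits)
  rep$deviation <- abs(rep$valence - rep$charge)
  if (length(d) == 0L) {
    rep$best_match <- FALSE
    best <- NA_character_
  } else {
    ord <- order(rep$deviation, rep$valence - rep$charge, rep$ion)
    best <- rep$ion[ord[1]]
    rep$best_match <- rep$ion == best
  }
  out <- as_tibble(rep[, c("ion", "charge", "valence", "valence_rounded",
                           "deviation", "best_match")])
  attr(out, "best_match") <- best
  attr(out, "n_contacts") <- length(d)
  class(out) <- c("valence_report", class(out))
  out
}

#' @export
print.valence_report <- function(x, ...) {
  cat("<valence_report> ", attr(x, "n_contacts"), " contact(s); best match: ",
      attr(x, "best_match"), "\n", sep = "")
  NextMethod()
}
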