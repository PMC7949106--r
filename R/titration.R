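#' Build a coupled protonation-titration system
#'
#' A titration system holds the ionizable sites of a protein (or a synthetic
#' stand-in), their model pKa values and intrinsic energy shifts, the
#' pairwise electrostatic couplings between their charged forms, and an
#' optional interaction with a bound monovalent cation.
#'
#' The microstate energy at a given pH is
#' \deqn{E(x) = \sum_i x_i [\ln(10) R T (pH - pKa_i) + s_i]
#'   + \sum_{i<j} q_i(x_i) q_j(x_j) W_{ij} + \sum_i q_i(x_i) \iota_i}
#' where `x_i` is 1 when site i is protonated, `q_i` is the site charge in
#' its current form (acid: 0 protonated / -1 deprotonated; base: +1 / 0),
#' `W` is the unit-charge screened-Coulomb factor between sites (kcal/mol;
#' the sign of each pair term comes from the current charges), and `iota`
#' is the analogous unit-charge factor to the bound ion, included only when
#' the ion is present. Raising the pH therefore disfavours protonation, and
#' an isolated site follows the Henderson-Hasselbalch curve exactly.
#'
#' @param sites A data frame with columns `label`, `kind` ("acid" or
#'   "base"), `pka`, and optionally `shift` (kcal/mol, default 0).
#' @param interaction Symmetric matrix (kcal/mol) with zero diagonal;
#'   `interaction[i, j]` is the unit-charge coupling between sites i and j.
#'   Default: no coupling.
#' @param ion_term Optional numeric vector: unit-charge screened-Coulomb
#'   factor between each site and a bound +1e ion (kcal/mol). Positive for
#'   a cation; the site's current charge supplies the sign of the energy.
#' @param temperature Kelvin; default 298.
#' @return A `titration_system`.
#' @examples
#' sys <- titration_system(data.frame(label = "ASP35", kind = "acid", pka = 4))
#' enumerate_exact(sys, pH = 5)
#' @export
titration_system <- function(sites, interaction = NULL, ion_term = NULL,
                             temperature = 298) {
  sites <- as_tibble(sites)
  stopifnot(all(c("label", "kind", "pka") %in% names(sites)),
            nrow(sites) >= 1L)
  if (!all(sites$kind %in% c("acid", "base"))) {
    abort("site kind must be 'acid' or 'base'")
  }
  if (!all(is.finite(sites$pka))) abort("model pKa values must be finite")
  if (!"shift" %in% names(sites)) sites$shift <- 0
  n <- nrow(sites)
  if (is.null(interaction)) interaction <- matrix(0, n, n)
  interaction <- as.matrix(interaction)
  if (!all(dim(interaction) == n)) abort("interaction matrix dimension mismatch")
  if (max(abs(interaction - t(interaction))) > 1e-9) {
    abort("interaction matrix must be symmetric")
  }
  if (any(abs(diag(interaction)) > 1e-12)) {
    abort("interaction matrix must have zero diagonal")
  }
  if (!is.null(ion_term)) {
    ion_term <- as.numeric(ion_term)
    if (length(ion_term) != n) abort("ion_term length must match sites")
  }
  stopifnot(temperature > 0)
  structure(
    list(sites = sites, interaction = interaction, ion_term = ion_term,
         temperature = temperature),
    class = "titration_system"
  )
}

#' @export
print.titration_system <- function(x, ...) {
  cat("<titration_system> ", nrow(x$sites), " site(s), T = ", x$temperature,
      " K, bound-ion term: ", ifelse(is.null(x$ion_term), "no", "yes"),
      "\n", sep = "")
  print(x$sites)
  invisible(x)
}

# Charges of all sites for a protonation vector x (1 = protonated)
site_charges <- function(system, x) {
  ifelse(system$sites$kind == "acid", x - 1, x)
}

# Per-site pH/shift energy of the protonated form, kcal/mol
ph_term <- function(system, pH) {
  log(10) * R_KCAL * system$temperature * (pH - system$sites$pka) +
    system$sites$shift
}

#' Energy of one protonation microstate
#'
#' @param system A [titration_system()].
#' @param state Binary vector, 1 = protonated, over the system's sites.
#' @param pH pH value.
#' @param ion_bound Include the bound-ion term? Requires `ion_term` in the
#'   system.
#' @return Energy in kcal/mol.
#' @export
microstate_energy <- function(system, state, pH, ion_bound = FALSE) {
  stopifnot(inherits(system, "titration_system"))
  n <- nrow(system$sites)
  state <- as.numeric(state)
  if (length(state) != n || !all(state %in% c(0, 1))) {
    abort("state must be a binary vector matching the system's sites")
  }
  if (ion_bound && is.null(system$ion_term)) {
    abort("system has no ion_term; cannot model the bound-ion condition")
  }
  q <- site_charges(system, state)
  e <- sum(state * ph_term(system, pH)) +
    sum((q %o% q) * system$interaction) / 2
  if (ion_bound) e <- e + sum(q * system$ion_term)
  e
}

#' Exact protonation probabilities by microstate enumeration
#'
#' Boltzmann-weights all `2^n` protonation microstates; serves as the
#' ground-truth oracle for [mc_titrate()]. Refuses systems with more than
#' 20 sites.
#'
#' @inheritParams microstate_energy
#' @param pH Numeric vector of pH values.
#' @return A tibble with columns `site`, `kind`, `pH`, `p` (protonation
#'   probability).
#' @export
enumerate_exact <- function(system, pH, ion_bound = FALSE) {
  stopifnot(inherits(system, "titration_system"))
  n <- nrow(system$sites)
  if (n > 20L) abort("exact enumeration limited to <= 20 sites (2^n states)")
  if (ion_bound && is.null(system$ion_term)) {
    abort("system has no ion_term; cannot model the bound-ion condition")
  }
  beta <- 1 / (R_KCAL * system$temperature)
  states <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))[, seq_len(n),
                                                          drop = FALSE]
  acid <- system$sites$kind == "acid"
  qmat <- states
  qmat[, acid] <- qmat[, acid, drop = FALSE] - 1
  e_pair <- rowSums((qmat %*% system$interaction) * qmat) / 2
  e_ion <- if (ion_bound) as.numeric(qmat %*% system$ion_term) else 0
  purrr::map_dfr(pH, function(ph) {
    e <- as.numeric(states %*% ph_term(system, ph)) + e_pair + e_ion
    logw <- -beta * e
    w <- exp(logw - logsumexp(logw))
    tibble(
      site = system$sites$label,
      kind = system$sites$kind,
      pH = ph,
      p = as.numeric(t(states) %*% w)
    )
  })
}

#' Metropolis Monte Carlo titration
#'
#' Samples protonation microstates at each requested pH with single-site
#' flips plus paired flips for strongly coupled site pairs (couplings
#' exceeding `pair_threshold` in magnitude trap single-flip chains in
#' carboxyl-carboxylate configurations). The protonation probability of
#' each site is the frequency of its protonated form after burn-in.
#'
#' @inheritParams enumerate_exact
#' @param sweeps Monte Carlo sweeps per pH (one sweep attempts a flip of
#'   every site, then every strongly coupled pair).
#' @param burn_in Sweeps discarded before accumulating occupancies;
#'   default 10\% of `sweeps`.
#' @param seed Integer seed; identical seed gives bit-identical occupancy
#'   counts.
#' @param pair_threshold kcal/mol; pairs with `|W| >` this get joint flips.
#' @return A `titration_fit`: tidy results in `$result` (site, pH, p, se,
#'   split-half halves and discrepancy) and per-pH diagnostics in
#'   `$diagnostics` (acceptance rate, sweeps kept). Also accessible via
#'   [tidy()] / [glance()].
#' @examples
#' sys <- titration_system(data.frame(label = "E1", kind = "acid", pka = 4))
#' fit <- mc_titrate(sys, pH = c(4, 5), sweeps = 2000, seed = 1)
#' tidy(fit)
#' @export
mc_titrate <- function(system, pH = c(5, 5.5, 6, 7, 7.5), sweeps = 10000,
                       burn_in = max(1L, sweeps %/% 10L), seed = 1,
                       ion_bound = FALSE, pair_threshold = 2) {
  stopifnot(inherits(system, "titration_system"))
  if (!(sweeps > burn_in && burn_in >= 0)) {
    abort("require sweeps > burn_in >= 0")
  }
  if (ion_bound && is.null(system$ion_term)) {
    abort("system has no ion_term; cannot model the bound-ion condition")
  }
  n <- nrow(system$sites)
  acid <- as.integer(system$sites$kind == "acid")
  w <- system$interaction
  ion <- if (ion_bound) system$ion_term else rep(0, n)
  pairs <- which(abs(w) > pair_threshold & upper.tri(w), arr.ind = TRUE)
  beta <- 1 / (R_KCAL * system$temperature)
  res <- with_seed(seed, {
    purrr::map(pH, function(ph) {
      out <- mc_titrate_cpp(ph_term(system, ph), acid, w, ion, beta,
                            as.integer(sweeps), as.integer(burn_in),
                            pairs - 1L)
      if (out$accepted == 0) {
        abort(paste0("frozen chain at pH ", ph,
                     ": no Monte Carlo move was accepted"))
      }
      out
    })
  })
  kept <- sweeps - burn_in
  result <- purrr::map2_dfr(res, pH, function(out, ph) {
    p <- out$counts / kept
    p1 <- out$counts_first / out$kept_first
    p2 <- out$counts_second / out$kept_second
    tibble(
      site = system$sites$label,
      kind = system$sites$kind,
      pH = ph,
      p = p,
      se = sqrt(pmax(p * (1 - p), 1e-12) / kept),
      p_first_half = p1,
      p_second_half = p2,
      split_half = abs(p1 - p2)
    )
  })
  diagnostics <- purrr::map2_dfr(res, pH, function(out, ph) {
    tibble(pH = ph, sweeps = sweeps, burn_in = burn_in,
           acceptance = out$accepted / out$attempted)
  })
  structure(
    list(result = result, diagnostics = diagnostics, seed = seed,
         ion_bound = ion_bound, system = system),
    class = "titration_fit"
  )
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("<titration_fit> ", nrow(x$system$sites), " site(s) x ",
      nrow(x$diagnostics), " pH value(s); seed ", x$seed,
      "; bound ion: ", x$ion_bound, "\n", sep = "")
  print(x$result)
  invisible(x)
}

#' Screened-Coulomb titration system from a structure
#'
#' Builds a [titration_system()] for all Asp, Glu and His residues of a
#' structure (Lys and Arg are treated as fixed protonated and are not
#' sampled). Couplings between charged-group centroids use a
#' Debye-screened Coulomb factor
#' `W_ij = 332.06 * exp(-r_ij / lambda) / (eps * r_ij)` kcal/mol per unit
#' charge pair; the signs enter through the sites' current charges. This is
#' a deliberately simple electrostatic model: externally computed intrinsic
#' shifts and interaction matrices can be supplied instead via
#' [read_energy_matrix()].
#'
#' @param structure A `mate_structure`.
#' @param eps Effective dielectric constant (default 10).
#' @param screening_length Debye length in Angstrom; `Inf` disables
#'   screening.
#' @param ion_position Optional 3-vector: position of a bound +1e cation;
#'   adds an `ion_term` computed the same way.
#' @param temperature Kelvin.
#' @param pka Named model-pKa table for the recognised residue types.
#' @return A `titration_system` whose site labels are `RES<number>` (e.g.
#'   `ASP35`).
#' @export
build_screened_coulomb_system <- function(structure, eps = 10,
                                          screening_length = Inf,
                                          ion_position = NULL,
                                          temperature = 298,
                                          pka = c(ASP = 4.0, GLU = 4.4,
                                                  HIS = 6.3)) {
  stopifnot(inherits(structure, "mate_structure"), eps > 0)
  a <- atoms(structure)
  a <- a[a$record_kind == "polymer" & a$residue_name %in% names(pka), ,
         drop = FALSE]
  if (nrow(a) == 0L) {
    abort("structure contains no ionizable (Asp/Glu/His) residues")
  }
  charged_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                        HIS = c("ND1", "NE2"))
  grp <- dplyr::group_by(a, .data$chain, .data$residue_number,
                         .data$residue_name)
  cent <- dplyr::summarise(grp, x = centroid_coord(.data$x, .data$name,
                                  charged_atoms[[.data$residue_name[1]]]),
                           y = centroid_coord(.data$y, .data$name,
                                  charged_atoms[[.data$residue_name[1]]]),
                           z = centroid_coord(.data$z, .data$name,
                                  charged_atoms[[.data$residue_name[1]]]),
                           .groups = "drop")
  n <- nrow(cent)
  sites <- tibble(
    label = paste0(cent$residue_name, cent$residue_number),
    kind = ifelse(cent$residue_name == "HIS", "base", "acid"),
    pka = unname(pka[cent$residue_name]),
    shift = 0
  )
  pos <- as.matrix(cent[, c("x", "y", "z")])
  w <- matrix(0, n, n)
  if (n > 1L) {
    d <- as.matrix(stats::dist(pos))
    off <- d > 0
    w[off] <- COULOMB_KCAL * exp(-d[off] / screening_length) /
      (eps * d[off])
  }
  ion_term <- NULL
  if (!is.null(ion_position)) {
    ion_position <- as.numeric(ion_position)
    stopifnot(length(ion_position) == 3L)
    r <- sqrt(rowSums(sweep(pos, 2, ion_position)^2))
    if (any(r <= 0)) abort("a site centroid coincides with the ion position")
    ion_term <- COULOMB_KCAL * exp(-r / screening_length) / (eps * r)
  }
  titration_system(sites, w, ion_term, temperature)
}

centroid_coord <- function(v, names, wanted) {
  sel <- names %in% wanted
  if (!any(sel)) sel <- rep(TRUE, length(v))
  mean(v[sel])
}

#' Read an externally computed titration energy matrix
#'
#' Importer for interaction/intrinsic-shift sets produced by an external
#' electrostatics solver. The file is tab- or comma-delimited with a header
#' and three blocks of rows identified by the `record` column:
#' `site` rows (`record, label, kind, pka, shift`), `pair` rows
#' (`record, label, label2, value` giving `W_ij` in kcal/mol), and optional
#' `ion` rows (`record, label, value`).
#'
#' @param file Path to the delimited file.
#' @param temperature Kelvin.
#' @return A [titration_system()].
#' @export
read_energy_matrix <- function(file, temperature = 298) {
  sep <- if (grepl("\\.csv$", file)) "," else "\t"
  raw <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, fill = TRUE)
  need <- c("record", "label", "label2", "pka", "shift", "kind", "value")
  for (col in setdiff(need, names(raw))) raw[[col]] <- NA
  s <- raw[raw$record == "site", , drop = FALSE]
  if (nrow(s) == 0L) abort("no 'site' rows in energy-matrix file")
  sites <- tibble(label = s$label, kind = s$kind,
                  pka = as.numeric(s$pka),
                  shift = ifelse(is.na(s$shift), 0, as.numeric(s$shift)))
  n <- nrow(sites)
  w <- matrix(0, n, n, dimnames = list(sites$label, sites$label))
  p <- raw[raw$record == "pair", , drop = FALSE]
  for (k in seq_len(nrow(p))) {
    i <- match(p$label[k], sites$label)
    j <- match(p$label2[k], sites$label)
    if (is.na(i) || is.na(j)) {
      abort(paste0("pair row refers to unknown site: ", p$label[k], "/",
                   p$label2[k]))
    }
    w[i, j] <- w[j, i] <- as.numeric(p$value[k])
  }
  ion <- NULL
  io <- raw[raw$record == "ion", , drop = FALSE]
  if (nrow(io)) {
    ion <- rep(0, n)
    ion[match(io$label, sites$label)] <- as.numeric(io$value)
  }
  titration_system(sites, w, ion, temperature)
}
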