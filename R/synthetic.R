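#' Generate a synthetic ion coordination site
#'
#' Places ligand oxygen atoms on an ideal coordination geometry at a mean
#' distance from the site centre, adds isotropic Gaussian positional noise,
#' and writes a central sodium `HETATM` at the centre — a fully known
#' stand-in for the five-ligand trigonal-bipyramidal sites observed in
#' MATE transporters. The truth record carries every quantity needed to
#' score downstream recovery.
#'
#' @param n_ligands Number of ligand atoms (default 5).
#' @param distance Mean centre-ligand distance, Angstrom (default 2.4).
#' @param noise Positional noise standard deviation per coordinate,
#'   Angstrom.
#' @param geometry `"trigonal-bipyramidal"` (default), `"octahedral"` or
#'   `"random"`.
#' @param center Site centre coordinates (kept away from the PDB origin so
#'   all fixed-width fields stay positive).
#' @param seed Integer seed; identical seed gives identical output.
#' @return A list: `structure` (a `mate_structure`), `pdb_text` (the
#'   PDB-format lines), `truth` (centre, centre serial, per-ligand true
#'   distances, geometry, seed).
#' @examples
#' site <- gen_coordination_site(seed = 1)
#' site$truth$distances
#' @export
gen_coordination_site <- function(n_ligands = 5, distance = 2.4, noise = 0,
                                  geometry = "trigonal-bipyramidal",
                                  center = c(20, 20, 20), seed = 1) {
  stopifnot(n_ligands >= 1, distance > 0, noise >= 0)
  dirs <- geometry_directions(n_ligands, geometry, seed)
  pos <- with_seed(seed, {
    sweep(distance * dirs, 2, center, `+`) +
      matrix(rnorm(3 * n_ligands, 0, noise), n_ligands, 3)
  })
  d_true <- sqrt(rowSums(sweep(pos, 2, center)^2))
  atoms <- tibble(
    serial = c(seq_len(n_ligands), n_ligands + 1L),
    name = c(rep("O", n_ligands), "NA"),
    element = c(rep("O", n_ligands), "NA"),
    residue_name = c(rep("GLY", n_ligands), "NA"),
    chain = "A",
    residue_number = c(seq_len(n_ligands), n_ligands + 1L),
    x = c(pos[, 1], center[1]),
    y = c(pos[, 2], center[2]),
    z = c(pos[, 3], center[3]),
    record_kind = c(rep("polymer", n_ligands), "hetero"),
    is_hydrogen = FALSE
  )
  s <- structure(list(atoms = atoms, id = paste0("synthetic-", geometry)),
                 class = "mate_structure")
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  write_pdb(s, tmp)
  list(
    structure = s,
    pdb_text = readLines(tmp),
    truth = list(center = center, center_serial = n_ligands + 1L,
                 distances = d_true, mean_distance = distance,
                 noise = noise, geometry = geometry,
                 directions = dirs, seed = seed)
  )
}

#' Generate a synthetic titration system with exact ground truth
#'
#' Random coupled acid/base systems whose exact per-site protonation
#' probabilities are attached by enumeration, for scoring the Monte Carlo
#' sampler.
#'
#' @param n_sites Number of ionizable sites.
#' @param pka_range Model pKa values drawn uniformly in this range.
#' @param coupling Scale (kcal/mol) of the pairwise unit-charge couplings,
#'   drawn from `Normal(0, coupling)` and symmetrized.
#' @param ion_term Add a bound-ion interaction (positive unit-charge
#'   factors drawn in `[0.5, 2]` kcal/mol)?
#' @param acid_fraction Probability a site is an acid (rest are bases).
#' @param pH pH grid for the attached exact truth.
#' @param temperature Kelvin.
#' @param seed Integer seed.
#' @return A list: `system` (a [titration_system()]), `truth` (exact per
#'   site/pH probabilities, for the no-ion condition and, when `ion_term`,
#'   the ion-bound condition), `seed`.
#' @export
gen_titration_system <- function(n_sites = 4, pka_range = c(3, 8),
                                 coupling = 1, ion_term = FALSE,
                                 acid_fraction = 0.7,
                                 pH = c(5, 5.5, 6, 7, 7.5),
                                 temperature = 298, seed = 1) {
  stopifnot(n_sites >= 1, coupling >= 0)
  sys <- with_seed(seed, {
    kind <- ifelse(runif(n_sites) < acid_fraction, "acid", "base")
    sites <- tibble(
      label = paste0(ifelse(kind == "acid", "ACID", "BASE"),
                     seq_len(n_sites)),
      kind = kind,
      pka = runif(n_sites, pka_range[1], pka_range[2]),
      shift = 0
    )
    w <- matrix(0, n_sites, n_sites)
    if (n_sites > 1L) {
      vals <- rnorm(n_sites * (n_sites - 1) / 2, 0, coupling)
      w[upper.tri(w)] <- vals
      w <- w + t(w)
    }
    ion <- if (ion_term) runif(n_sites, 0.5, 2) else NULL
    titration_system(sites, w, ion, temperature)
  })
  truth <- if (n_sites <= 20L) {
    t0 <- enumerate_exact(sys, pH, ion_bound = FALSE)
    t0$condition <- "apo"
    if (ion_term) {
      t1 <- enumerate_exact(sys, pH, ion_bound = TRUE)
      t1$condition <- "ion-bound"
      t0 <- dplyr::bind_rows(t0, t1)
    }
    t0
  }
  list(system = sys, truth = truth, seed = seed)
}

#' Generate a synthetic coordinate trajectory
#'
#' Emits a [coord_series()] for an ion coordinated by five ligands:
#' `"stable"` draws Gaussian jitter about the reference geometry for every
#' frame; `"escape"` keeps the ion bound until `escape_frame`, then drifts
#' it away until it sits beyond 8 Angstrom from the site centre — the
#' signature of a ligand that dissociates once unrestrained.
#'
#' @param kind `"stable"` or `"escape"`.
#' @param n_frames Number of frames (>= 2).
#' @param sigma Positional fluctuation per coordinate, Angstrom.
#' @param escape_frame Frame at which the ion starts leaving (required for
#'   `"escape"`; must lie inside the trajectory).
#' @param distance Reference ion-ligand distance, Angstrom.
#' @param dt Frame spacing, ns.
#' @param seed Integer seed.
#' @return A list: `series` (selections `ion`, `lig1..lig5`, `site_center`),
#'   `truth` (reference distances, sigma, escape frame, seed).
#' @export
gen_trajectory <- function(kind = c("stable", "escape"), n_frames = 1000,
                           sigma = 0.1, escape_frame = NULL, distance = 2.3,
                           dt = 0.1, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n_frames >= 2, sigma >= 0)
  if (kind == "escape") {
    if (is.null(escape_frame) || escape_frame < 1 ||
        escape_frame > n_frames) {
      abort("escape_frame must lie within the trajectory")
    }
  }
  dirs <- geometry_directions(5, "trigonal-bipyramidal")
  lig_ref <- distance * dirs
  series <- with_seed(seed, {
    rows <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      ion <- rnorm(3, 0, sigma)
      if (kind == "escape" && f >= escape_frame) {
        # unbinding: immediate exit past 8 A, then a slow outward drift
        ion <- ion + c(min(10 + 0.1 * (f - escape_frame), 14), 0, 0)
      }
      lig <- lig_ref + matrix(rnorm(15, 0, sigma), 5, 3)
      rows[[f]] <- tibble(
        frame = f, time = (f - 1) * dt,
        selection = c("ion", paste0("lig", 1:5), "site_center"),
        x = c(ion[1], lig[, 1], 0),
        y = c(ion[2], lig[, 2], 0),
        z = c(ion[3], lig[, 3], 0)
      )
    }
    dplyr::bind_rows(rows)
  })
  list(
    series = coord_series(series),
    truth = list(kind = kind, reference_distances = rep(distance, 5),
                 sigma = sigma, escape_frame = escape_frame,
                 seed = seed)
  )
}

#' Generate an apo / ion-added pair of DEER traces
#'
#' Simulates two conditions from a shared set of Gaussian distance
#' components: the second condition moves `shift` of the probability mass
#' from the shortest-distance component to the longest one, emulating the
#' reweighting toward longer distances seen when Na+ is added. Both traces
#' share the time grid, noise level and background model.
#'
#' @param model_apo A [deer_model()]; default two components (3.0 and
#'   4.5 nm, widths 0.3 nm, weights 0.7/0.3, depth 0.3).
#' @param shift Probability mass moved to the long-distance component,
#'   in `[0, min(weight_short)]`.
#' @param noise Gaussian noise standard deviation (default 0.005).
#' @param t Time grid, microseconds.
#' @param seed Integer seed.
#' @return A list: `traces` (named list `apo`, `plus_na`), `truth` (both
#'   generating models and the shift), `seed`.
#' @export
gen_deer_pair <- function(model_apo = NULL, shift = 0.3, noise = 0.005,
                          t = seq(0, 2.5, by = 0.01), seed = 1) {
  model_apo <- model_apo %||% deer_model(
    tibble(mean = c(3.0, 4.5), width = 0.3, weight = c(0.7, 0.3)),
    depth = 0.3, bg_k = 0.05
  )
  comp <- model_apo$components
  stopifnot(shift >= 0, shift <= 1)
  k <- nrow(comp)
  if (k < 2L && shift > 0) abort("weight shift needs >= 2 components")
  comp_b <- comp
  if (shift > 0) {
    if (comp$weight[1] < shift) {
      abort("shift exceeds the short-distance component's weight")
    }
    comp_b$weight[1] <- comp$weight[1] - shift
    comp_b$weight[k] <- comp$weight[k] + shift
  }
  model_b <- deer_model(comp_b, depth = model_apo$depth,
                        bg_k = model_apo$bg_k, bg_d = model_apo$bg_d)
  traces <- list(
    apo = simulate_trace(model_apo, t, noise, seed = seed,
                         condition = "apo"),
    plus_na = simulate_trace(model_b, t, noise,
                             seed = seed + 104729L,
                             condition = "plus_na")
  )
  list(traces = traces,
       truth = list(model_apo = model_apo, model_plus_na = model_b,
                    shift = shift, noise = noise, seed = seed),
       seed = seed)
}

#' Write a generator's truth record as JSON
#'
#' Every generator output carries a machine-readable truth record; this
#' writes it next to an artifact so recovery scoring never needs to parse
#' logs. The file is named deterministically from the artifact path
#' (`<path>.truth.json`).
#'
#' @param truth A truth record (list) from a generator.
#' @param path Artifact path the truth belongs to.
#' @return The truth-file path, invisibly.
#' @export
write_truth <- function(truth, path) {
  truth_path <- paste0(path, ".truth.json")
  jsonlite::write_json(sanitize_for_json(truth), truth_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth_path)
}

sanitize_for_json <- function(x) {
  if (inherits(x, "deer_model")) {
    return(list(components = as.data.frame(x$components), depth = x$depth,
                bg_k = x$bg_k, bg_d = x$bg_d))
  }
  if (is.matrix(x)) return(apply(x, 1, as.numeric, simplify = FALSE))
  if (is.list(x)) return(lapply(x, sanitize_for_json))
  x
}
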