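#' Ion species for alchemical transformations
#'
#' Built-in Lennard-Jones parameters for the two cations of interest
#' (CHARMM-like values: Na+ radius 1.36 A, well depth 0.047 kcal/mol;
#' K+ 1.76 A, 0.087 kcal/mol). The alchemical path interpolates radius and
#' well depth linearly between two species; the charge (+1e) is common so
#' electrostatic terms cancel along the path.
#'
#' @param label `"Na+"` or `"K+"`, or any label when `radius`/`well_depth`
#'   are supplied.
#' @param radius,well_depth Override the built-in values (Angstrom,
#'   kcal/mol).
#' @return A list with `label`, `radius`, `well_depth`, `charge`.
#' @export
ion_species <- function(label, radius = NULL, well_depth = NULL) {
  builtin <- list(
    "Na+" = list(radius = 1.36, well_depth = 0.047),
    "K+"  = list(radius = 1.76, well_depth = 0.087)
  )
  if (is.null(radius) || is.null(well_depth)) {
    if (!label %in% names(builtin)) {
      abort(paste0("unknown ion '", label,
                   "'; supply radius and well_depth explicitly"))
    }
    radius <- radius %||% builtin[[label]]$radius
    well_depth <- well_depth %||% builtin[[label]]$well_depth
  }
  stopifnot(radius > 0, well_depth >= 0)
  list(label = label, radius = radius, well_depth = well_depth, charge = 1)
}

#' Toy single-ion binding cage
#'
#' A desk-scale surrogate for a five-ligand trigonal-bipyramidal ion site:
#' fixed reference ligand centres carrying partial charges and
#' Lennard-Jones spheres, a harmonic cage confining the mobile ion near the
#' site centre, and (optionally mobile) ligands tethered to their reference
#' positions. The energy is
#' `sum_i [ eps_i ((Rmin_i/r_i)^12 - 2 (Rmin_i/r_i)^6) + 332.06 q q_i / r_i ]
#'  + k_cage |x_ion|^2 + k_ligand sum_i |X_i - X_i^ref|^2`,
#' with `Rmin_i = radius_ion + radius_i` and
#' `eps_i = sqrt(well_ion * well_i)`.
#'
#' @param n_ligands Number of ligand centres (default 5).
#' @param distance Reference ligand distance from the centre, Angstrom.
#' @param geometry `"trigonal-bipyramidal"`, `"octahedral"` or `"random"`.
#' @param ligand_charge Partial charge per ligand (default -0.34, a
#'   carbonyl-like oxygen softened for the toy cage).
#' @param ligand_radius,ligand_well_depth Per-ligand LJ parameters
#'   (recycled).
#' @param cage_k Harmonic cage stiffness on the ion, kcal/mol/A^2.
#' @param ligand_k Harmonic tether stiffness on each mobile ligand.
#' @param mobile_ligands Sample ligand positions as well as the ion?
#' @param temperature Kelvin.
#' @param seed Seed for the `"random"` geometry.
#' @return A `toy_site`.
#' @examples
#' toy_site()
#' @export
toy_site <- function(n_ligands = 5, distance = 2.3,
                     geometry = c("trigonal-bipyramidal", "octahedral",
                                  "random"),
                     ligand_charge = -0.34, ligand_radius = 1.7,
                     ligand_well_depth = 0.12, cage_k = 10, ligand_k = 2,
                     mobile_ligands = TRUE, temperature = 298, seed = 1) {
  geometry <- match.arg(geometry)
  stopifnot(n_ligands >= 0, distance > 0, cage_k > 0, ligand_k >= 0,
            temperature > 0)
  centers <- if (n_ligands > 0) {
    distance * geometry_directions(n_ligands, geometry, seed)
  } else {
    matrix(numeric(0), 0, 3)
  }
  structure(
    list(
      ligand_centers = centers,
      ligand_charge = rep_len(ligand_charge, n_ligands),
      ligand_radius = rep_len(ligand_radius, n_ligands),
      ligand_well_depth = rep_len(ligand_well_depth, n_ligands),
      cage_k = cage_k, ligand_k = ligand_k,
      mobile_ligands = mobile_ligands && n_ligands > 0,
      temperature = temperature
    ),
    class = "toy_site"
  )
}

#' @rdname toy_site
#' @details `bulk_site()` is the solution-phase reference leg: an isotropic
#'   harmonic cage with no specific ligands. Because the alchemical path
#'   only touches ion-ligand terms, the bulk leg's energy differences vanish
#'   identically and it serves as an exact null reference.
#' @param site Site whose cage stiffness and temperature to copy.
#' @export
bulk_site <- function(site = NULL, cage_k = 10, temperature = 298) {
  if (!is.null(site)) {
    cage_k <- site$cage_k
    temperature <- site$temperature
  }
  toy_site(n_ligands = 0, cage_k = cage_k, mobile_ligands = FALSE,
           temperature = temperature)
}

# Unit direction vectors for ideal coordination geometries.
geometry_directions <- function(n, geometry, seed = 1) {
  ideal <- switch(
    geometry,
    "trigonal-bipyramidal" = rbind(
      c(0, 0, 1), c(0, 0, -1),
      c(1, 0, 0), c(-1 / 2, sqrt(3) / 2, 0), c(-1 / 2, -sqrt(3) / 2, 0)
    ),
    "octahedral" = rbind(
      c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
      c(0, 0, 1), c(0, 0, -1)
    ),
    "random" = NULL
  )
  if (is.null(ideal)) {
    return(with_seed(seed, {
      v <- matrix(rnorm(3 * n), n, 3)
      v / sqrt(rowSums(v^2))
    }))
  }
  if (n > nrow(ideal)) {
    abort(paste0("geometry '", geometry, "' supports at most ", nrow(ideal),
                 " ligands"))
  }
  ideal[seq_len(n), , drop = FALSE]
}

#' @export
print.toy_site <- function(x, ...) {
  cat("<toy_site> ", nrow(x$ligand_centers), " ligand(s), cage k = ",
      x$cage_k, " kcal/mol/A^2, ligands ",
      if (x$mobile_ligands) "mobile" else "fixed", ", T = ", x$temperature,
      " K\n", sep = "")
  invisible(x)
}

#' Flat-harmonic distance restraints between ligand centres
#'
#' Each restraint is zero within `width` of the reference distance and
#' harmonic (`0.5 k (|d - d_ref| - width)^2`) outside that window; this is
#' the flat-harmonic form used to hold a binding site near its experimental
#' geometry during alchemical transformations.
#'
#' @param site A [toy_site()].
#' @param k Force constant, kcal/mol/A^2 (default 120).
#' @param width Flat half-width, Angstrom (default 0.5).
#' @param pairs Two-column matrix of ligand indices. Default: the four
#'   geometry-defining distances of a five-ligand trigonal bipyramid (the
#'   axial pair and the three equatorial pairs); for other sites, all
#'   ligand pairs.
#' @return A `restraint_set` tibble with columns `i`, `j`, `reference`,
#'   `width`, `k`.
#' @export
restraint_set <- function(site, k = 120, width = 0.5, pairs = NULL) {
  stopifnot(inherits(site, "toy_site"), k >= 0, width >= 0)
  n <- nrow(site$ligand_centers)
  if (n < 2L) abort("restraints need at least two ligands")
  if (is.null(pairs)) {
    pairs <- if (n == 5L) {
      rbind(c(1, 2), c(3, 4), c(4, 5), c(3, 5))
    } else {
      t(utils::combn(n, 2))
    }
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  ref <- vapply(seq_len(nrow(pairs)), function(r) {
    sqrt(sum((site$ligand_centers[pairs[r, 1], ] -
                site$ligand_centers[pairs[r, 2], ])^2))
  }, numeric(1))
  out <- tibble(i = pairs[, 1], j = pairs[, 2], reference = ref,
                width = width, k = k)
  class(out) <- c("restraint_set", class(out))
  out
}

#' Alchemical window schedule
#'
#' The default mirrors a 50-window protocol with the first third of each
#' window discarded as equilibration.
#'
#' @param n_windows Number of lambda windows partitioning `[0, 1]`.
#' @param steps_per_window Monte Carlo steps per window.
#' @param equilibration_fraction Fraction of each window discarded.
#' @return A `fep_schedule` list.
#' @export
fep_schedule <- function(n_windows = 50, steps_per_window = 30000,
                         equilibration_fraction = 1 / 3) {
  stopifnot(n_windows >= 1, steps_per_window > 0,
            equilibration_fraction >= 0, equilibration_fraction < 1)
  structure(list(n_windows = as.integer(n_windows),
                 steps_per_window = as.integer(steps_per_window),
                 equilibration_fraction = equilibration_fraction),
            class = "fep_schedule")
}

interp_ion <- function(ion_a, ion_b, lambda) {
  list(
    radius = (1 - lambda) * ion_a$radius + lambda * ion_b$radius,
    well_depth = (1 - lambda) * ion_a$well_depth + lambda * ion_b$well_depth,
    charge = (1 - lambda) * ion_a$charge + lambda * ion_b$charge
  )
}

restraint_matrix <- function(restraints) {
  if (is.null(restraints) || nrow(restraints) == 0L) {
    return(matrix(numeric(0), 0, 5))
  }
  cbind(restraints$i - 1, restraints$j - 1, restraints$reference,
        restraints$width, restraints$k)
}

default_tracked_pairs <- function(site) {
  n <- nrow(site$ligand_centers)
  if (n < 2L) return(matrix(numeric(0), 0, 2))
  if (n == 5L) rbind(c(1, 2), c(3, 4), c(4, 5), c(3, 5)) else
    t(utils::combn(n, 2))
}

#' Sample one alchemical window
#'
#' Metropolis sampling of the ion position (and ligand positions, when the
#' site's ligands are mobile) with the ion's Lennard-Jones parameters set
#' by `lambda`, recording the energy difference to the `lambda_next`
#' parameters for every post-equilibration step.
#'
#' @param site A [toy_site()].
#' @param lambda,lambda_next Coupling parameter of the sampled and the
#'   target window, in `[0, 1]` along the `ion_a -> ion_b` path.
#' @param ion_a,ion_b End-point [ion_species()].
#' @param restraints Optional [restraint_set()].
#' @param steps Monte Carlo steps.
#' @param equilibration_fraction Initial fraction discarded.
#' @param seed Integer seed (bit-identical sample stream on rerun).
#' @param step_ion,step_ligand Maximum displacement per move, Angstrom.
#' @param tracked_pairs Ligand index pairs whose mean distances are
#'   recorded (defaults to the four geometry-defining distances).
#' @return A list: `du` (energy-difference samples, kcal/mol),
#'   `acceptance`, `ion_mean`, `ion_var` (per-coordinate), `mean_distances`
#'   for the tracked pairs, and the window metadata.
#' @export
sample_window <- function(site, lambda, lambda_next, ion_a, ion_b,
                          restraints = NULL, steps = 30000,
                          equilibration_fraction = 1 / 3, seed = 1,
                          step_ion = 0.25, step_ligand = 0.12,
                          tracked_pairs = NULL) {
  stopifnot(inherits(site, "toy_site"), steps > 0,
            lambda >= 0, lambda <= 1, lambda_next >= 0, lambda_next <= 1)
  tracked_pairs <- tracked_pairs %||% default_tracked_pairs(site)
  p0 <- interp_ion(ion_a, ion_b, lambda)
  p1 <- interp_ion(ion_a, ion_b, lambda_next)
  n_equil <- floor(steps * equilibration_fraction)
  out <- with_seed(seed, {
    toy_fep_window_cpp(
      site$ligand_centers, site$ligand_charge, site$ligand_radius,
      site$ligand_well_depth, site$mobile_ligands, site$cage_k,
      site$ligand_k,
      c(p0$radius, p0$well_depth, p0$charge),
      c(p1$radius, p1$well_depth, p1$charge),
      restraint_matrix(restraints),
      matrix(as.integer(tracked_pairs), ncol = 2) - 1L,
      as.integer(steps), as.integer(n_equil),
      1 / (R_KCAL * site$temperature), step_ion, step_ligand
    )
  })
  if (out$acceptance < 0.01) {
    warn(sprintf("window lambda = %.3f: acceptance rate %.1f%% (< 1%%)",
                 lambda, 100 * out$acceptance))
  }
  out$lambda <- lambda
  out$lambda_next <- lambda_next
  out
}

#' Zwanzig exponential-averaging free-energy estimator
#'
#' `dG = -RT log( mean exp(-dU / RT) )`, overflow-guarded by a max-shift.
#'
#' @param du Energy-difference samples, kcal/mol.
#' @param temperature Kelvin.
#' @return Free-energy difference, kcal/mol.
#' @export
zwanzig <- function(du, temperature = 298) {
  du <- as.numeric(du)
  if (length(du) == 0L) abort("zwanzig estimator needs at least one sample")
  rt <- R_KCAL * temperature
  x <- -du / rt
  m <- max(x)
  -rt * (m + log(mean(exp(x - m))))
}

#' Relative binding free energy by double alchemical transformation
#'
#' Runs the full protocol on the toy model: the bound ion is transformed
#' `ion_a -> ion_b` in the binding site while the reference leg performs
#' the same transformation in the bulk cage, in `n_windows` consecutive
#' lambda windows; the process is then reversed and the free energy
#' recomputed. The relative binding free energy is
#' `ddG = dG_site(A->B) - dG_bulk(A->B)`; a positive value for
#' `ion_a = Na+`, `ion_b = K+` means the site is selective for Na+ over
#' K+. Each leg reports its forward estimate, the backward estimate (on
#' the reverse path), their mean `dG_mean = (dG_forward - dG_backward)/2`
#' and the hysteresis `dG_forward + dG_backward` (near 0 when converged).
#' When ligands are mobile, mean tracked distances in the pure `ion_a` and
#' pure `ion_b` ensembles yield the binding-site deformation statistics of
#' [geometry_change()].
#'
#' @inheritParams sample_window
#' @param schedule A [fep_schedule()].
#' @param bulk The solution leg, a [bulk_site()] by default.
#' @param hysteresis_tol kcal/mol; larger per-leg hysteresis attaches a
#'   convergence warning (non-fatal).
#' @param seed Integer seed controlling all windows.
#' @return A `fep_result`: per-window table in `$windows`, per-leg
#'   summaries in `$legs`, the headline `$ddg`, `$geometry` (a
#'   [geometry_change()] when ligands are mobile), `$fold_preference` at
#'   the site temperature, `$warnings`.
#' @examples
#' res <- run_ddg(toy_site(mobile_ligands = FALSE),
#'                schedule = fep_schedule(10, 2000), seed = 1)
#' glance(res)
#' @export
run_ddg <- function(site, ion_a = ion_species("Na+"),
                    ion_b = ion_species("K+"), schedule = fep_schedule(),
                    restraints = NULL, bulk = bulk_site(site), seed = 1,
                    step_ion = 0.25, step_ligand = 0.12,
                    hysteresis_tol = 1) {
  stopifnot(inherits(site, "toy_site"), inherits(schedule, "fep_schedule"))
  nw <- schedule$n_windows
  lam <- seq(0, 1, length.out = nw + 1L)
  envs <- list(site = site, bulk = bulk)
  warnings <- character(0)
  rows <- list()
  legs <- list()
  geom_means <- list()
  for (env_name in names(envs)) {
    env <- envs[[env_name]]
    for (direction in c("forward", "backward")) {
      path <- if (direction == "forward") lam else rev(lam)
      dgs <- numeric(nw)
      for (k in seq_len(nw)) {
        wseed <- (seed * 1000L + match(env_name, names(envs)) * 100L +
                    match(direction, c("forward", "backward")) * 10L + k) %%
          .Machine$integer.max
        win <- sample_window(env, path[k], path[k + 1L], ion_a, ion_b,
                             restraints = if (env_name == "site") restraints,
                             steps = schedule$steps_per_window,
                             equilibration_fraction =
                               schedule$equilibration_fraction,
                             seed = wseed, step_ion = step_ion,
                             step_ligand = step_ligand)
        dgs[k] <- zwanzig(win$du, env$temperature)
        rows[[length(rows) + 1L]] <- tibble(
          env = env_name, direction = direction, window = k,
          lambda_from = path[k], lambda_to = path[k + 1L], dg = dgs[k],
          acceptance = win$acceptance, n_samples = length(win$du)
        )
        if (env_name == "site" && k == 1L) {
          key <- if (direction == "forward") "a" else "b"
          geom_means[[key]] <- win$mean_distances
        }
      }
      legs[[paste(env_name, direction, sep = "_")]] <- sum(dgs)
    }
  }
  leg_tab <- tibble(
    env = names(envs),
    dg_forward = c(legs$site_forward, legs$bulk_forward),
    dg_backward = c(legs$site_backward, legs$bulk_backward)
  )
  leg_tab$dg_mean <- (leg_tab$dg_forward - leg_tab$dg_backward) / 2
  leg_tab$hysteresis <- leg_tab$dg_forward + leg_tab$dg_backward
  bad <- abs(leg_tab$hysteresis) > hysteresis_tol
  if (any(bad)) {
    warnings <- c(warnings, sprintf(
      "hysteresis %.3f kcal/mol on %s leg exceeds %.2f: increase sampling",
      leg_tab$hysteresis[bad], leg_tab$env[bad], hysteresis_tol))
  }
  ddg <- leg_tab$dg_mean[leg_tab$env == "site"] -
    leg_tab$dg_mean[leg_tab$env == "bulk"]
  geometry <- NULL
  if (site$mobile_ligands && length(geom_means) == 2L &&
      length(geom_means$a) >= 2L) {
    geometry <- geometry_change(geom_means$a, geom_means$b)
  }
  structure(
    list(windows = dplyr::bind_rows(rows), legs = leg_tab, ddg = ddg,
         ion_a = ion_a$label, ion_b = ion_b$label, geometry = geometry,
         fold_preference = fold_preference(ddg, site$temperature),
         restrained = !is.null(restraints), seed = seed,
         schedule = schedule, temperature = site$temperature,
         warnings = warnings),
    class = "fep_result"
  )
}

#' @export
print.fep_result <- function(x, ...) {
  cat("<fep_result> ", x$ion_a, " -> ", x$ion_b,
      if (x$restrained) " (restrained)" else " (unrestrained)", "\n",
      sep = "")
  print(x$legs)
  cat(sprintf("ddG = %.3f kcal/mol; fold preference %.1f at %g K\n",
              x$ddg, x$fold_preference, x$temperature))
  if (!is.null(x$geometry)) {
    cat(sprintf("site deformation: dD = %.3f A, ddD = %.3f A (N = %d)\n",
                x$geometry$dD, x$geometry$ddD, x$geometry$n))
  }
  for (w in x$warnings) cat("warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Binding-site deformation statistics
#'
#' For per-distance ensemble means in two ion-bound states, computes
#' `dd_i = <d_i(A)> - <d_i(B)>`, the mean absolute change
#' `dD = (1/N) sum |dd_i|` and its spread
#' `ddD = sqrt( (1/(N(N-1))) sum (|dd_i| - dD)^2 )`.
#'
#' @param distances_a,distances_b Equal-length numeric vectors of mean
#'   distances (Angstrom) in states A and B; `N >= 2`.
#' @return A `geometry_change` list: `delta_d`, `dD`, `ddD`, `n`.
#' @examples
#' geometry_change(c(2.4, 2.6, 2.4, 2.6), c(2.3, 2.3, 2.3, 2.3))
#' @export
geometry_change <- function(distances_a, distances_b) {
  a <- as.numeric(distances_a)
  b <- as.numeric(distances_b)
  if (length(a) != length(b)) abort("mean-distance vectors differ in length")
  n <- length(a)
  if (n < 2L) abort("ddD is undefined for fewer than 2 distances")
  dd <- a - b
  d_mean <- mean(abs(dd))
  spread <- sqrt(sum((abs(dd) - d_mean)^2) / (n * (n - 1)))
  structure(list(delta_d = dd, dD = d_mean, ddD = spread, n = n),
            class = "geometry_change")
}

#' @export
print.geometry_change <- function(x, ...) {
  cat(sprintf("<geometry_change> N = %d: dD = %.4f A, ddD = %.4f A\n",
              x$n, x$dD, x$ddD))
  invisible(x)
}

#' Boltzmann fold preference implied by a selectivity free energy
#'
#' `exp(ddG / (R T))`: the occupancy ratio the free-energy penalty
#' translates into at equilibrium. A 2.5 kcal/mol penalty against K+ at
#' 298 K corresponds to a ~68-fold preference for Na+.
#'
#' @param ddg Relative binding free energy, kcal/mol.
#' @param temperature Kelvin.
#' @return Dimensionless fold preference.
#' @export
fold_preference <- function(ddg, temperature = 298) {
  stopifnot(temperature > 0)
  exp(ddg / (R_KCAL * temperature))
}

#' Toy-site free energy by direct configuration-integral quadrature
#'
#' Independent oracle for rigid-ligand toys: evaluates
#' `dG = -RT log( Z_B / Z_A )` with `Z = int exp(-U(x)/RT) dx` over a 3-D
#' grid for the single mobile ion.
#'
#' @inheritParams sample_window
#' @param half_width Half-width of the cubic integration box, Angstrom.
#' @param n_grid Grid points per dimension.
#' @return Free-energy difference `ion_a -> ion_b`, kcal/mol.
#' @export
quadrature_dg <- function(site, ion_a, ion_b, half_width = 4, n_grid = 161) {
  stopifnot(inherits(site, "toy_site"))
  if (site$mobile_ligands) {
    abort("quadrature oracle applies to rigid-ligand sites only")
  }
  g <- seq(-half_width, half_width, length.out = n_grid)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  rt <- R_KCAL * site$temperature
  u <- function(ion) {
    e <- site$cage_k * rowSums(pts^2)
    for (i in seq_len(nrow(site$ligand_centers))) {
      r <- sqrt(rowSums(sweep(pts, 2, site$ligand_centers[i, ])^2))
      r <- pmax(r, 1e-6)
      rmin <- ion$radius + site$ligand_radius[i]
      epsij <- sqrt(ion$well_depth * site$ligand_well_depth[i])
      e <- e + epsij * ((rmin / r)^12 - 2 * (rmin / r)^6) +
        COULOMB_KCAL * ion$charge * site$ligand_charge[i] / r
    }
    e
  }
  ea <- u(ion_a)
  eb <- u(ion_b)
  m <- min(ea)
  -rt * (log(sum(exp(-(eb - m) / rt))) - log(sum(exp(-(ea - m) / rt))))
}
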