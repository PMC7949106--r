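# Shared fixtures, built in code.

# A minimal fixed-column PDB ATOM/HETATM line writer for hand-built inputs.
pdb_line <- function(record = "ATOM", serial = 1, name = "CA",
                     resname = "ALA", chain = "A", resno = 1,
                     x = 0, y = 0, z = 0, altloc = " ", element = NULL) {
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_fmt, altloc, resname, chain, resno,
          x, y, z, 1, 0, element %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent term-by-term microstate-energy oracle (plain loops, no reuse
# of package internals beyond the constants).
energy_oracle <- function(sites, w, ion, state, pH, temperature = 298,
                          ion_bound = FALSE) {
  rt <- 1.9872e-3 * temperature
  n <- nrow(sites)
  q <- numeric(n)
  e <- 0
  for (i in seq_len(n)) {
    if (state[i] == 1) {
      e <- e + log(10) * rt * (pH - sites$pka[i]) + sites$shift[i]
    }
    q[i] <- if (sites$kind[i] == "acid") state[i] - 1 else state[i]
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) e <- e + q[i] * q[j] * w[i, j]
    }
  }
  if (ion_bound) for (i in seq_len(n)) e <- e + q[i] * ion[i]
  e
}

# Carboxyl-carboxylate pair emulating the N-lobe aspartates with a bound
# cation next to the first acid: strong coupling forces single protonation.
carboxyl_pair_system <- function() {
  titration_system(
    data.frame(label = c("ASP35", "ASP178"), kind = "acid", pka = 4),
    interaction = matrix(c(0, 11, 11, 0), 2),
    ion_term = c(10, 0)
  )
}

# Energy of the toy binding cage, written out independently from the
# documented functional form (oracle for the compiled sampler).
toy_energy_oracle <- function(site, ion, ion_pos, lig_pos = NULL) {
  lig_pos <- lig_pos %||% site$ligand_centers
  e <- site$cage_k * sum(ion_pos^2)
  for (i in seq_len(nrow(lig_pos))) {
    r <- sqrt(sum((ion_pos - lig_pos[i, ])^2))
    rmin <- ion$radius + site$ligand_radius[i]
    epsij <- sqrt(ion$well_depth * site$ligand_well_depth[i])
    e <- e + epsij * ((rmin / r)^12 - 2 * (rmin / r)^6) +
      332.06 * ion$charge * site$ligand_charge[i] / r
    e <- e + site$ligand_k * sum((lig_pos[i, ] - site$ligand_centers[i, ])^2)
  }
  e
}

# Grid quadrature of the configuration-integral ratio for a rigid toy
# (independent free-energy oracle).
quad_oracle <- function(site, ion_a, ion_b, half_width = 4, n_grid = 121) {
  g <- seq(-half_width, half_width, length.out = n_grid)
  pts <- as.matrix(expand.grid(g, g, g))
  rt <- 1.9872e-3 * site$temperature
  usite <- function(ion) {
    e <- site$cage_k * rowSums(pts^2)
    for (i in seq_len(nrow(site$ligand_centers))) {
      r <- pmax(sqrt(rowSums(sweep(pts, 2, site$ligand_centers[i, ])^2)),
                1e-6)
      rmin <- ion$radius + site$ligand_radius[i]
      epsij <- sqrt(ion$well_depth * site$ligand_well_depth[i])
      e <- e + epsij * ((rmin / r)^12 - 2 * (rmin / r)^6) +
        332.06 * ion$charge * site$ligand_charge[i] / r
    }
    e
  }
  ea <- usite(ion_a)
  eb <- usite(ion_b)
  m <- min(ea)
  -rt * (log(sum(exp(-(eb - m) / rt))) - log(sum(exp(-(ea - m) / rt))))
}

# Brute-force dipolar kernel column by composite trapezoid quadrature.
kernel_oracle <- function(t, r, n_x = 200001) {
  x <- seq(0, 1, length.out = n_x)
  w <- rep(1, n_x)
  w[c(1, n_x)] <- 0.5
  w <- w / sum(w)
  omega <- 2 * pi * 52.04 / r^3
  vapply(t, function(tt) sum(w * cos((1 - 3 * x^2) * omega * tt)),
         numeric(1))
}
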