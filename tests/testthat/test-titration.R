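test_that("a lone acid at its pKa has equal-energy protonation states", {
  sys <- titration_system(data.frame(label = "D1", kind = "acid", pka = 4.5))
  expect_equal(microstate_energy(sys, 1, pH = 4.5), 0, tolerance = 1e-12)
  expect_equal(microstate_energy(sys, 0, pH = 4.5), 0, tolerance = 1e-12)
})

test_that("two deprotonated acids with W = 3 pay the pairwise penalty", {
  sys <- titration_system(data.frame(label = c("D1", "D2"), kind = "acid",
                                     pka = 4),
                          interaction = matrix(c(0, 3, 3, 0), 2))
  expect_equal(microstate_energy(sys, c(0, 0), pH = 4), 3, tolerance = 1e-12)
  expect_equal(microstate_energy(sys, c(1, 1), pH = 4), 0, tolerance = 1e-12)
})

test_that("microstate energies equal an independent term-by-term oracle", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    sites <- data.frame(
      label = paste0("S", 1:n),
      kind = sample(c("acid", "base"), n, replace = TRUE),
      pka = runif(n, 3, 9), shift = rnorm(n, 0, 0.8)
    )
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- rnorm(n * (n - 1) / 2, 0, 2)
    w <- w + t(w)
    ion <- runif(n, 0, 2)
    sys <- titration_system(sites, w, ion)
    state <- sample(0:1, n, replace = TRUE)
    ph <- runif(1, 3, 9)
    for (bound in c(FALSE, TRUE)) {
      expect_equal(
        microstate_energy(sys, state, ph, ion_bound = bound),
        energy_oracle(sites, w, ion, state, ph, ion_bound = bound),
        tolerance = 1e-10
      )
    }
  }
})

test_that("exact enumeration reproduces Henderson-Hasselbalch", {
  sys <- titration_system(data.frame(label = "D", kind = "acid", pka = 4))
  expect_equal(enumerate_exact(sys, 4)$p, 0.5, tolerance = 1e-12)
  expect_equal(enumerate_exact(sys, 5)$p, 1 / (1 + 10), tolerance = 1e-12)
  for (ph in seq(2, 8, by = 0.5)) {
    expect_equal(enumerate_exact(sys, ph)$p, 1 / (1 + 10^(ph - 4)),
                 tolerance = 1e-10)
  }
  b <- titration_system(data.frame(label = "H", kind = "base", pka = 6.3))
  for (ph in c(5, 6.3, 7.5)) {
    expect_equal(enumerate_exact(b, ph)$p, 1 / (1 + 10^(ph - 6.3)),
                 tolerance = 1e-10)
  }
})

test_that("coupled acid pair matches explicit 4-state hand enumeration", {
  pka <- 4; w12 <- 3; ph <- 7; t <- 298
  sys <- titration_system(data.frame(label = c("A", "B"), kind = "acid",
                                     pka = pka),
                          interaction = matrix(c(0, w12, w12, 0), 2),
                          temperature = t)
  rt <- 1.9872e-3 * t
  h <- log(10) * rt * (ph - pka)
  e <- c(`00` = w12, `10` = h, `01` = h, `11` = 2 * h)
  wgt <- exp(-e / rt)
  wgt <- wgt / sum(wgt)
  p1 <- wgt["10"] + wgt["11"]
  got <- enumerate_exact(sys, ph)
  expect_equal(got$p, unname(c(p1, p1)), tolerance = 1e-12)
})

test_that("strong coupling leaves exactly one proton shared by the pair", {
  sys <- titration_system(data.frame(label = c("A", "B"), kind = "acid",
                                     pka = 4),
                          interaction = matrix(c(0, 5, 5, 0), 2))
  p <- enumerate_exact(sys, 5)$p
  expect_equal(sum(p), 1, tolerance = 0.05)      # one proton in the pair
  expect_true(all(p > 0.3 & p < 0.7))            # shared, not localized
})

test_that("Monte Carlo occupancies track exact enumeration across systems", {
  n_ok <- 0L
  n_tot <- 0L
  for (s in 1:5) {
    g <- gen_titration_system(n_sites = 8, coupling = 1, seed = s)
    exact <- enumerate_exact(g$system, 7)
    fit <- mc_titrate(g$system, 7, sweeps = 10000, seed = 100 + s)
    kept <- 10000 - 1000
    se <- sqrt(pmax(exact$p * (1 - exact$p), 1e-12) / kept)
    ok <- abs(tidy(fit)$p - exact$p) <= 3 * se
    n_ok <- n_ok + sum(ok)
    n_tot <- n_tot + length(ok)
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("without couplings every site follows its own titration curve", {
  g <- gen_titration_system(n_sites = 5, coupling = 0, seed = 3)
  fit <- mc_titrate(g$system, pH = c(4, 6, 8), sweeps = 8000, seed = 7)
  d <- tidy(fit)
  hh <- 1 / (1 + 10^(d$pH - g$system$sites$pka[match(d$site,
                                              g$system$sites$label)]))
  expect_true(all(abs(d$p - hh) <= pmax(3 * sqrt(hh * (1 - hh) / 7200),
                                        0.005)))
})

test_that("a bound cation suppresses protonation of an isolated acid", {
  sys <- titration_system(data.frame(label = "A", kind = "acid", pka = 6),
                          ion_term = 2)
  p_apo <- enumerate_exact(sys, 6, ion_bound = FALSE)$p
  p_ion <- enumerate_exact(sys, 6, ion_bound = TRUE)$p
  expect_lt(p_ion, p_apo)
  # monotone in the ion-term magnitude
  prev <- p_apo
  for (iota in c(0.5, 1, 2, 4)) {
    s <- titration_system(data.frame(label = "A", kind = "acid", pka = 6),
                          ion_term = iota)
    p <- enumerate_exact(s, 6, ion_bound = TRUE)$p
    expect_lt(p, prev)
    prev <- p
  }
})

test_that("the ion-bound carboxyl pair keeps one acid protonated", {
  sys <- carboxyl_pair_system()
  exact <- enumerate_exact(sys, 7, ion_bound = TRUE)
  expect_gt(exact$p[exact$site == "ASP178"], 0.99)
  expect_lt(exact$p[exact$site == "ASP35"], 0.01)
  fit <- mc_titrate(sys, 7, sweeps = 20000, seed = 3, ion_bound = TRUE)
  d <- tidy(fit)
  expect_gt(d$p[d$site == "ASP178"], 0.99)
  expect_lt(d$p[d$site == "ASP35"], 0.01)
})

test_that("identical seeds give bit-identical Monte Carlo results", {
  g <- gen_titration_system(n_sites = 6, coupling = 1.5, seed = 4)
  f1 <- mc_titrate(g$system, c(5, 7), sweeps = 4000, seed = 99)
  f2 <- mc_titrate(g$system, c(5, 7), sweeps = 4000, seed = 99)
  expect_identical(tidy(f1), tidy(f2))
  f3 <- mc_titrate(g$system, c(5, 7), sweeps = 4000, seed = 100)
  expect_false(identical(tidy(f1)$p, tidy(f3)$p))
})

test_that("split-half discrepancy and acceptance diagnostics are reported", {
  g <- gen_titration_system(n_sites = 4, seed = 8)
  fit <- mc_titrate(g$system, 7, sweeps = 6000, seed = 2)
  expect_true(all(is.finite(tidy(fit)$split_half)))
  gl <- glance(fit)
  expect_true(all(gl$acceptance > 0 & gl$acceptance <= 1))
  expect_true(all(gl$max_split_half >= 0))
})

test_that("screened-Coulomb builder computes the documented couplings", {
  # two aspartates with carboxylate centroids exactly 8 A apart
  txt <- c(
    pdb_line("ATOM", 1, "OD1", "ASP", "A", 1, 0, 0, 0, element = "O"),
    pdb_line("ATOM", 2, "OD2", "ASP", "A", 1, 0, 0, 0, element = "O"),
    pdb_line("ATOM", 3, "OD1", "ASP", "A", 5, 8, 0, 0, element = "O"),
    pdb_line("ATOM", 4, "OD2", "ASP", "A", 5, 8, 0, 0, element = "O")
  )
  s <- read_pdb(paste(txt, collapse = "\n"))
  sys <- build_screened_coulomb_system(s, eps = 10)
  expect_equal(sys$sites$label, c("ASP1", "ASP5"))
  expect_equal(sys$interaction[1, 2], 332.06 / (10 * 8), tolerance = 1e-10)
  # Debye screening shrinks the coupling
  scr <- build_screened_coulomb_system(s, eps = 10, screening_length = 8)
  expect_equal(scr$interaction[1, 2], 332.06 * exp(-1) / 80,
               tolerance = 1e-10)
  # bound ion adds a positive unit-charge factor
  ion_sys <- build_screened_coulomb_system(s, eps = 10,
                                           ion_position = c(4, 0, 0))
  expect_equal(ion_sys$ion_term, rep(332.06 / 40, 2), tolerance = 1e-10)
})

test_that("single-residue structures give an empty interaction matrix", {
  txt <- pdb_line("ATOM", 1, "OE1", "GLU", "A", 9, 0, 0, 0, element = "O")
  sys <- build_screened_coulomb_system(read_pdb(txt))
  expect_equal(dim(sys$interaction), c(1L, 1L))
  expect_true(all(sys$interaction == 0))
  expect_error(
    build_screened_coulomb_system(
      read_pdb(pdb_line("ATOM", 1, "CA", "ALA", "A", 1))),
    "ionizable"
  )
})

test_that("external energy matrices import into equivalent systems", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "record\tlabel\tlabel2\tkind\tpka\tshift\tvalue",
    "site\tASP35\t\tacid\t4\t0\t",
    "site\tHIS352\t\tbase\t6.3\t0.5\t",
    "pair\tASP35\tHIS352\t\t\t\t-1.25",
    "ion\tASP35\t\t\t\t\t2.0"
  ), f)
  sys <- read_energy_matrix(f)
  expect_equal(sys$sites$label, c("ASP35", "HIS352"))
  expect_equal(sys$interaction[1, 2], -1.25)
  expect_equal(sys$ion_term, c(2, 0))
  expect_equal(sys$sites$shift, c(0, 0.5))
  unlink(f)
})

test_that("invalid systems and states are rejected", {
  expect_error(titration_system(data.frame(label = "X", kind = "weird",
                                           pka = 4)), "acid")
  expect_error(
    titration_system(data.frame(label = c("A", "B"), kind = "acid", pka = 4),
                     interaction = matrix(c(0, 1, 2, 0), 2)),
    "symmetric")
  expect_error(
    titration_system(data.frame(label = "A", kind = "acid", pka = 4),
                     interaction = matrix(1, 1, 1)),
    "diagonal")
  sys <- titration_system(data.frame(label = "A", kind = "acid", pka = 4))
  expect_error(microstate_energy(sys, c(1, 0), 7), "binary")
  expect_error(enumerate_exact(sys, 7, ion_bound = TRUE), "ion_term")
  expect_error(mc_titrate(sys, 7, sweeps = 100, burn_in = 200), "burn_in")
  big <- gen_titration_system(n_sites = 21, seed = 1)
  expect_error(enumerate_exact(big$system, 7), "20 sites")
})
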