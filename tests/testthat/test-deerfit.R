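test_that("dipolar kernel is 1 at t = 0 and matches brute-force quadrature", {
  t <- seq(0, 2, by = 0.02)
  r <- c(1.5, 2, 3, 4.5, 6)
  K <- dipolar_kernel(t, r)
  expect_equal(K[1, ], rep(1, length(r)), tolerance = 1e-12)
  for (j in c(2, 3, 5)) {
    expect_lt(max(abs(K[, j] - kernel_oracle(t, r[j]))), 1e-6)
  }
  expect_error(dipolar_kernel(t, c(3, -1)), "positive")
})

test_that("dipolar frequency scales as 1/r^3: halving r speeds it 8-fold", {
  t <- seq(0, 3, by = 5e-4)
  K <- dipolar_kernel(t, c(2, 4))
  first_min <- function(v) t[which(diff(sign(diff(v))) > 0)[1] + 1L]
  t2 <- first_min(K[, 1])
  t4 <- first_min(K[, 2])
  expect_equal(t4 / t2, 8, tolerance = 0.02)
})

test_that("simulated traces follow the forward model", {
  m <- deer_model(data.frame(mean = 3, width = 0.05, weight = 1),
                  depth = 0.3, bg_k = 0.08)
  t <- seq(0, 2, by = 0.01)
  r <- seq(1, 8, by = 0.02)
  tr <- simulate_trace(m, t, noise = 0, r_grid = r)
  expect_equal(tr$amplitude[1], 1, tolerance = 1e-9)
  # direct composition: background x (1 - depth + depth * K P)
  K <- dipolar_kernel(t, r)
  p <- dnorm(r, 3, 0.05)
  wtr <- matekit:::trapezoid_weights(r)
  p <- p / sum(wtr * p)
  v <- exp(-0.08 * t) * (1 - 0.3 + 0.3 * as.numeric(K %*% (p * wtr)))
  expect_equal(tr$amplitude, v, tolerance = 1e-10)

  # depth 0 leaves only the background
  m0 <- deer_model(data.frame(mean = 3, width = 0.3, weight = 1),
                   depth = 1e-12, bg_k = 0.08)
  expect_error(deer_model(data.frame(mean = 3, width = 0.3, weight = 1),
                          depth = 0), "depth")
  tr0 <- simulate_trace(m0, t, noise = 0)
  expect_equal(tr0$amplitude, exp(-0.08 * t), tolerance = 1e-9)

  # seeded noise is bit-reproducible
  a <- simulate_trace(m, t, noise = 0.01, seed = 11)
  b <- simulate_trace(m, t, noise = 0.01, seed = 11)
  expect_identical(a$amplitude, b$amplitude)
})

test_that("noiseless single-Gaussian traces are recovered near-exactly", {
  truth <- deer_model(data.frame(mean = 3.4, width = 0.28, weight = 1),
                      depth = 0.35, bg_k = 0.06)
  tr <- simulate_trace(truth, seq(0, 2, by = 0.012), noise = 0)
  fit <- fit_mixture(tr, max_components = 3, seed = 1)
  expect_equal(fit$selected_k, 1L)
  comp <- tidy(fit)
  expect_lt(abs(comp$mean - 3.4), 0.02)
  expect_lt(abs(comp$mean - 3.4) / 3.4, 1e-3)
  expect_lt(abs(comp$width - 0.28) / 0.28, 0.01)
  expect_lt(abs(comp$depth - 0.35), 0.005)
})

test_that("two-condition global fits recover means and the weight shift", {
  for (s in c(3, 4, 5)) {
    pair <- gen_deer_pair(shift = 0.3, noise = 0.005, seed = s)
    fit <- fit_mixture(pair$traces, max_components = 3, seed = 1)
    expect_equal(fit$selected_k, 2L)
    comp <- tidy(fit)
    apo <- comp[comp$condition == "apo", ]
    plus <- comp[comp$condition == "plus_na", ]
    expect_lt(abs(apo$mean[1] - 3.0), 0.1)
    expect_lt(abs(apo$mean[2] - 4.5), 0.1)
    # mass moves toward the long-distance component on Na+ addition
    expect_gt(plus$weight[2], apo$weight[2])
    # and the mean distance increases accordingly
    stats <- lapply(fit$distributions, distribution_stats)
    expect_gt(stats$plus_na$mean, stats$apo$mean)
  }
})

test_that("model selection does not overfit single-component data", {
  hits <- 0L
  for (s in 1:10) {
    truth <- deer_model(data.frame(mean = 3.6, width = 0.3, weight = 1),
                        depth = 0.3, bg_k = 0.05)
    tr <- simulate_trace(truth, seq(0, 1.8, by = 0.015), noise = 0.005,
                         seed = 1000 + s)
    fit <- fit_mixture(tr, max_components = 3, seed = 1, n_starts = 2)
    hits <- hits + (fit$selected_k == 1L)
  }
  expect_gte(hits, 9L)
})

test_that("every fitted distribution is normalized and banded", {
  pair <- gen_deer_pair(seed = 21)
  fit <- fit_mixture(pair$traces, max_components = 2, seed = 2)
  for (d in fit$distributions) {
    expect_equal(matekit:::trapz_integral(d$r, d$p), 1, tolerance = 1e-6)
    expect_true(all(d$lower <= d$p + 1e-12))
    expect_true(all(d$p <= d$upper + 1e-12))
    expect_true(all(d$lower >= 0))
  }
})

test_that("hand-built models yield zero-width bands", {
  m <- deer_model(data.frame(mean = c(3, 4.5), width = 0.3,
                             weight = c(0.6, 0.4)))
  b <- confidence_band(m)
  expect_equal(b$lower, b$p)
  expect_equal(b$upper, b$p)
  expect_equal(matekit:::trapz_integral(b$r, b$p), 1, tolerance = 1e-6)
})

test_that("noisier data widen the confidence band", {
  widths <- sapply(c(0.004, 0.008), function(noise) {
    per_seed <- sapply(1:7, function(s) {
      truth <- deer_model(data.frame(mean = 3.5, width = 0.3, weight = 1),
                          depth = 0.3, bg_k = 0.05)
      tr <- simulate_trace(truth, seq(0, 1.5, by = 0.015), noise = noise,
                           seed = 300 + s)
      fit <- fit_mixture(tr, max_components = 1, seed = 1, n_starts = 1)
      d <- fit$distributions[[1]]
      sel <- d$p > 0.1 * max(d$p)
      median(d$upper[sel] - d$lower[sel])
    })
    median(per_seed)
  })
  expect_gt(widths[2], widths[1])
})

test_that("delta-method band agrees with a parametric bootstrap", {
  truth <- deer_model(data.frame(mean = 3.5, width = 0.3, weight = 1),
                      depth = 0.3, bg_k = 0.05)
  tgrid <- seq(0, 1.5, by = 0.015)
  tr <- simulate_trace(truth, tgrid, noise = 0.006, seed = 17)
  fit <- fit_mixture(tr, max_components = 1, seed = 1, n_starts = 1)
  d0 <- fit$distributions[[1]]
  m0 <- fit$models[[1]]
  boot <- sapply(1:200, function(b) {
    trb <- simulate_trace(m0, tgrid, noise = 0.006, seed = 5000 + b)
    fb <- fit_mixture(trb, max_components = 1, seed = 1, n_starts = 1)
    fb$distributions[[1]]$p
  })
  boot_half <- 2 * apply(boot, 1, sd)
  delta_half <- (d0$upper - d0$lower) / 2
  sel <- d0$p > 0.1 * max(d0$p)
  rel <- abs(delta_half[sel] - boot_half[sel]) /
    pmax(boot_half[sel], 1e-12)
  expect_lt(median(rel), 0.25)
})

test_that("fits are deterministic under a fixed seed", {
  pair <- gen_deer_pair(seed = 31)
  f1 <- fit_mixture(pair$traces, max_components = 2, seed = 5)
  f2 <- fit_mixture(pair$traces, max_components = 2, seed = 5)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$selected_k, f2$selected_k)
})

test_that("traces read back from delimited text round-trip", {
  m <- deer_model(data.frame(mean = 3.2, width = 0.3, weight = 1))
  tr <- simulate_trace(m, seq(0, 1, 0.01), noise = 0.003, seed = 9,
                       condition = "apo")
  f <- tempfile(fileext = ".dat")
  write.table(data.frame(tr$time, tr$amplitude), f, col.names = FALSE,
              row.names = FALSE)
  back <- read_deer_trace(f, condition = "apo")
  expect_equal(back$amplitude, tr$amplitude, tolerance = 1e-12)
  expect_equal(attr(back, "condition"), "apo")
  unlink(f)
})

test_that("model construction enforces its invariants", {
  expect_error(deer_model(data.frame(mean = 3, width = -0.1, weight = 1)),
               "width")
  expect_error(deer_model(data.frame(mean = 3, width = 0.3, weight = 0.7)),
               "sum to 1")
  expect_error(deer_model(data.frame(mean = 3, width = 0.3, weight = 1),
                          bg_k = -1), "background")
})
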