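make_two_atom_series <- function(n = 10, sep = 3) {
  coord_series(dplyr::bind_rows(lapply(seq_len(n), function(f) {
    tibble::tibble(frame = f, time = f - 1,
                   selection = c("a", "b"),
                   x = c(0, sep), y = 0, z = 0)
  })))
}

test_that("static atom pairs give a constant distance series", {
  ds <- distance_series(make_two_atom_series(10, 3), "a", "b")
  expect_equal(ds$distance, rep(3, 10))
  expect_equal(ds$frame, 1:10)
})

test_that("jittered trajectories recover the generator's mean distance", {
  g <- gen_trajectory("stable", n_frames = 5000, sigma = 0.1, seed = 2)
  ds <- distance_series(g$series, "ion", "lig1")
  # ion and ligand each jitter with sigma = 0.1 about a 2.3 A separation
  expect_lt(abs(mean(ds$distance) - 2.3), 0.02)
  expect_equal(nrow(ds), 5000L)
})

test_that("escape trajectories step at the known frame", {
  g <- gen_trajectory("escape", n_frames = 300, sigma = 0.1,
                      escape_frame = 100, seed = 3)
  ds <- distance_series(g$series, "ion", "site_center")
  expect_true(all(ds$distance[1:99] < 2))
  expect_true(all(ds$distance[100:300] > 8))
  expect_equal(detect_escape(ds, threshold = 5), 100L)
  expect_error(gen_trajectory("escape", n_frames = 50, escape_frame = 80),
               "escape_frame")
})

test_that("probability distributions are density-normalized", {
  # constant series: one occupied bin of density 1/bin_width
  h <- prob_distribution(rep(2.5, 100), bin_width = 0.1)
  expect_equal(sum(h$density > 0), 1L)
  expect_equal(max(h$density), 1 / 0.1, tolerance = 1e-12)
  expect_equal(sum(h$density) * 0.1, 1, tolerance = 1e-9)

  set.seed(8)
  d <- rnorm(10000, 2.3, 0.15)
  h2 <- prob_distribution(d, bin_width = 0.05)
  expect_equal(sum(h2$density) * 0.05, 1, tolerance = 1e-9)
  expect_lt(abs(attr(h2, "mean") - 2.3), 3 * 0.15 / sqrt(10000))
  expect_lt(abs(attr(h2, "sd") - 0.15), 0.01)
})

test_that("two-state series split bin mass by occupancy", {
  set.seed(4)
  n <- 10000
  state <- runif(n) < 0.8
  d <- ifelse(state, 2.3, 4.1) + rnorm(n, 0, 0.02)
  h <- prob_distribution(d, bin_width = 0.2)
  short_mass <- sum(h$density[h$mid < 3]) * 0.2
  p_hat <- mean(state)
  expect_lt(abs(short_mass - p_hat), 1e-9)       # binning splits cleanly
  expect_lt(abs(short_mass - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})

test_that("burn-in discards initial frames and empty windows error", {
  d <- c(rep(10, 50), rep(2, 50))
  h <- prob_distribution(d, bin_width = 0.1, burn_in = 50)
  expect_true(all(h$mid < 3))
  expect_error(prob_distribution(d, burn_in = 100), "burn-in")
})

test_that("nearest-distance series finds the pinned candidate", {
  set.seed(6)
  n_cand <- 50
  rows <- list()
  for (f in 1:100) {
    far <- matrix(rnorm(3 * n_cand, 0, 1), ncol = 3)
    far <- far / sqrt(rowSums(far^2)) * runif(n_cand, 5, 12)
    if (f < 50) far[1, ] <- c(2, 0, 0)   # pinned candidate, removed at 50
    rows[[f]] <- tibble::tibble(
      frame = f, time = f,
      selection = c("center", paste0("wat", seq_len(n_cand))),
      x = c(0, far[, 1]), y = c(0, far[, 2]), z = c(0, far[, 3])
    )
  }
  series <- coord_series(dplyr::bind_rows(rows))
  nd <- nearest_distance_series(series, "center", "^wat", regex = TRUE)
  expect_equal(nd$distance[1:49], rep(2, 49))
  expect_true(all(nd$distance[50:100] >= 5))
  expect_equal(nd$nearest[1], "wat1")

  # single candidate degenerates to the plain pair distance
  two <- make_two_atom_series(5, 4)
  nd1 <- nearest_distance_series(two, "a", "b")
  expect_equal(nd1$distance, distance_series(two, "a", "b")$distance)
  expect_error(nearest_distance_series(two, "a", character(0)), "empty")
})

test_that("nearest distance is bounded by any single-member distance", {
  g <- gen_trajectory("stable", n_frames = 200, sigma = 0.2, seed = 9)
  nd <- nearest_distance_series(g$series, "ion", paste0("lig", 1:5))
  for (l in paste0("lig", 1:5)) {
    ds <- distance_series(g$series, "ion", l)
    expect_true(all(nd$distance <= ds$distance + 1e-12))
  }
})

test_that("density maps integrate to the mean selection size", {
  g <- gen_trajectory("stable", n_frames = 2000, sigma = 0.5, seed = 5)
  grid <- density_map(g$series, "ion", spacing = 0.5)
  spacing <- attr(grid, "spacing")
  expect_equal(sum(grid$density) * spacing^3, 1, tolerance = 1e-6)
  # a static atom occupies a single voxel
  still <- make_two_atom_series(50, 3)
  g1 <- density_map(still, "a", spacing = 0.5)
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$count, 50L)
})

test_that("an isotropic Gaussian cloud yields the expected radial mass", {
  set.seed(12)
  n <- 10000
  pts <- matrix(rnorm(3 * n, 0, 0.5), ncol = 3)
  rows <- tibble::tibble(frame = seq_len(n), time = seq_len(n),
                         selection = "g",
                         x = pts[, 1], y = pts[, 2], z = pts[, 3])
  grid <- density_map(coord_series(rows), "g", spacing = 0.25)
  r_vox <- sqrt(grid$x^2 + grid$y^2 + grid$z^2)
  # mass inside r < 0.5 (one sigma) vs chi(3) expectation
  inner <- sum(grid$count[r_vox < 0.5]) / n
  p_expected <- stats::pchisq(1, df = 3)
  expect_lt(abs(inner - p_expected), 0.05)
})

test_that("rigid-body alignment removes a global rotation", {
  g <- gen_trajectory("stable", n_frames = 500, sigma = 0.1, seed = 7)
  base <- g$series
  rotated <- dplyr::group_modify(
    dplyr::group_by(base, .data$frame), function(d, key) {
      th <- 0.01 * key$frame
      rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
                    3, 3)
      xyz <- as.matrix(d[, c("x", "y", "z")]) %*% t(rot)
      d$x <- xyz[, 1]; d$y <- xyz[, 2]; d$z <- xyz[, 3]
      d
    })
  rotated <- coord_series(dplyr::ungroup(rotated))
  # track an off-axis equatorial ligand: the rotation sweeps it over an arc
  aligned <- density_map(rotated, "lig3", spacing = 0.5,
                         align = paste0("lig", 1:5))
  plain <- density_map(base, "lig3", spacing = 0.5)
  # same occupied extent and center of mass within a voxel
  com <- function(g) colSums(g$count * cbind(g$x, g$y, g$z)) / sum(g$count)
  expect_lt(sqrt(sum((com(aligned) - com(plain))^2)), 0.5)
  expect_equal(sum(aligned$count), sum(plain$count))
  unaligned <- density_map(rotated, "lig3", spacing = 0.5)
  expect_gt(nrow(unaligned), nrow(aligned))  # rotation smears the cloud
})

test_that("Kabsch superposition matches the bio3d reference", {
  set.seed(10)
  p <- matrix(rnorm(30), 10, 3)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  q <- p %*% t(rot) + matrix(rep(c(1, -2, 0.5), each = 10), 10, 3)
  fit <- matekit:::kabsch(p, q)
  moved <- matekit:::apply_rigid(p, fit)
  expect_lt(max(abs(moved - q)), 1e-10)
  # independent route: bio3d least-squares fit of the same point sets
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(q)),
                   mobile = matrix(as.numeric(t(p)), nrow = 1)))
  expect_lt(max(abs(matrix(ref, ncol = 3, byrow = TRUE) - q)), 1e-6)
})

test_that("degenerate alignment selections are rejected", {
  still <- make_two_atom_series(10, 3)
  expect_error(density_map(still, "a", align = c("a", "b")), "non-collinear")
  expect_error(density_map(still, "missing"), "not found")
  expect_error(distance_series(still, "a", "zzz"), "not found")
})

test_that("coordinate tables round-trip through delimited text", {
  g <- gen_trajectory("stable", n_frames = 20, sigma = 0.05, seed = 4)
  f <- tempfile(fileext = ".tsv")
  write.table(as.data.frame(g$series), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read_coords(f)
  expect_equal(nrow(back), nrow(g$series))
  ds1 <- distance_series(g$series, "ion", "lig1")
  ds2 <- distance_series(back, "ion", "lig1")
  expect_equal(ds1$distance, ds2$distance, tolerance = 1e-12)
  unlink(f)
})
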