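#' Coordinate time series
#'
#' The native trajectory format is a tidy table with one row per (frame,
#' selection): columns `frame` (integer), `time` (ns; defaults to `frame`),
#' `selection` (atom or group name), `x`, `y`, `z` (Angstrom). A selection
#' may have several rows per frame (a group); distance operators then use
#' its centroid.
#'
#' @param df Data frame with the columns above.
#' @return A validated `coord_series` tibble.
#' @export
coord_series <- function(df) {
  df <- as_tibble(df)
  need <- c("frame", "selection", "x", "y", "z")
  if (!all(need %in% names(df))) {
    abort(paste0("coordinate series needs columns: ",
                 paste(need, collapse = ", ")))
  }
  if (!"time" %in% names(df)) df$time <- as.numeric(df$frame)
  if (nrow(df) == 0L) abort("coordinate series has no frames")
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))) {
    abort("coordinates must be finite")
  }
  class(df) <- unique(c("coord_series", class(df)))
  df
}

#' @rdname coord_series
#' @param file Delimited text file (tab or comma) with a header row naming
#'   the columns above.
#' @export
read_coords <- function(file) {
  sep <- if (grepl("\\.csv$", file)) "," else ""
  coord_series(utils::read.table(file, header = TRUE, sep = sep,
                                 stringsAsFactors = FALSE))
}

# centroid per frame for one selection; error names the missing frame
selection_points <- function(series, selection, frames = NULL) {
  s <- series[series$selection == selection, , drop = FALSE]
  if (nrow(s) == 0L) abort(paste0("selection '", selection, "' not found"))
  g <- dplyr::summarise(dplyr::group_by(s, .data$frame),
                        time = .data$time[1], x = mean(.data$x),
                        y = mean(.data$y), z = mean(.data$z),
                        .groups = "drop")
  if (!is.null(frames)) {
    missing <- setdiff(frames, g$frame)
    if (length(missing)) {
      abort(paste0("selection '", selection, "' missing in frame ",
                   missing[1]))
    }
  }
  g
}

#' Per-frame distance between two selections
#'
#' Euclidean distance between the centroids of two selections in every
#' frame, e.g. an ion-ligand coordination distance along a trajectory.
#'
#' @param series A [coord_series()].
#' @param a,b Selection names.
#' @param label Pair label stored on the result.
#' @return A `distance_series` tibble: `frame`, `time`, `distance`.
#' @export
distance_series <- function(series, a, b, label = paste(a, b, sep = "-")) {
  frames <- sort(unique(series$frame))
  pa <- selection_points(series, a, frames)
  pb <- selection_points(series, b, frames)
  j <- dplyr::inner_join(pa, pb, by = "frame", suffix = c("_a", "_b"))
  out <- tibble(
    frame = j$frame, time = j$time_a,
    distance = sqrt((j$x_a - j$x_b)^2 + (j$y_a - j$y_b)^2 +
                      (j$z_a - j$z_b)^2)
  )
  attr(out, "pair") <- label
  class(out) <- c("distance_series", class(out))
  out
}

#' Per-frame distance to the nearest member of a candidate group
#'
#' For every frame, the minimum distance from the centre selection to any
#' of the candidate selections — e.g. the distance from a binding-site
#' centre to the nearest water molecule, whose jump signals ligand escape.
#'
#' @param series A [coord_series()].
#' @param center Selection name of the centre.
#' @param candidates Character vector of candidate selection names, or a
#'   regular expression (used when `regex = TRUE`) matched against all
#'   selection names.
#' @param regex Interpret `candidates` as a regular expression?
#' @return A `distance_series` tibble with an extra `nearest` column.
#' @export
nearest_distance_series <- function(series, center, candidates,
                                    regex = FALSE) {
  if (regex) {
    candidates <- grep(candidates, setdiff(unique(series$selection), center),
                       value = TRUE)
  }
  if (length(candidates) == 0L) abort("candidate group is empty")
  frames <- sort(unique(series$frame))
  pc <- selection_points(series, center, frames)
  cand <- series[series$selection %in% candidates, , drop = FALSE]
  if (nrow(cand) == 0L) abort("no candidate selections present")
  cents <- dplyr::summarise(
    dplyr::group_by(cand, .data$frame, .data$selection),
    x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
    .groups = "drop")
  per_frame <- dplyr::group_by(
    dplyr::inner_join(cents, pc, by = "frame", suffix = c("", "_c")),
    .data$frame)
  per_frame <- dplyr::mutate(per_frame,
    d = sqrt((.data$x - .data$x_c)^2 + (.data$y - .data$y_c)^2 +
               (.data$z - .data$z_c)^2))
  nearest <- dplyr::slice_min(per_frame, .data$d, n = 1, with_ties = FALSE)
  nearest <- dplyr::ungroup(nearest)
  missing <- setdiff(frames, nearest$frame)
  if (length(missing)) {
    abort(paste0("candidate group empty in frame ", missing[1]))
  }
  nearest <- nearest[order(nearest$frame), ]
  out <- tibble(frame = nearest$frame, time = nearest$time,
                distance = nearest$d, nearest = nearest$selection)
  attr(out, "pair") <- paste0(center, "-nearest")
  class(out) <- c("distance_series", class(out))
  out
}

#' Distance probability distribution
#'
#' Density-normalized histogram of a distance series
#' (`sum(density) * bin_width = 1`), the per-distance view used to judge
#' whether a bound ion stays coordinated over a trajectory.
#'
#' @param ds A `distance_series` (or numeric vector of distances).
#' @param bin_width Angstrom (default 0.1).
#' @param burn_in Frames discarded from the start.
#' @return A `distance_histogram` tibble: `mid`, `count`, `density`, with
#'   attributes `mean`, `mode`, `bin_width`, `n`.
#' @export
prob_distribution <- function(ds, bin_width = 0.1, burn_in = 0) {
  d <- if (is.numeric(ds)) ds else ds$distance
  stopifnot(bin_width > 0, burn_in >= 0)
  if (burn_in >= length(d)) abort("no frames left after burn-in")
  d <- d[(burn_in + 1):length(d)]
  lo <- floor(min(d) / bin_width) * bin_width
  breaks <- seq(lo, max(d) + bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  out <- tibble(mid = h$mids, count = h$counts,
                density = h$counts / (length(d) * bin_width))
  attr(out, "mean") <- mean(d)
  attr(out, "sd") <- sd(d)
  attr(out, "mode") <- h$mids[which.max(h$counts)]
  attr(out, "bin_width") <- bin_width
  attr(out, "n") <- length(d)
  class(out) <- c("distance_histogram", class(out))
  out
}

# Kabsch least-squares superposition: rotation + translation mapping P
# (n x 3) onto Q. No scaling; proper rotation enforced via the sign of the
# smallest singular value.
kabsch <- function(p, q) {
  stopifnot(nrow(p) == nrow(q), nrow(p) >= 3L)
  cp <- colMeans(p)
  cq <- colMeans(q)
  h <- crossprod(sweep(p, 2, cp), sweep(q, 2, cq))
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = rot, translation = as.numeric(cq - rot %*% cp))
}

apply_rigid <- function(xyz, fit) {
  sweep(xyz %*% t(fit$rotation), 2, -fit$translation)
}

#' 3-D occupancy density map
#'
#' Bins a selection's positions on a cubic voxel grid after optional
#' rigid-body superposition of every frame onto a reference frame
#' (Kabsch least squares on a named alignment selection, no scaling).
#' Densities are normalized by frame count and voxel volume, so the map
#' integrates to the mean number of selected atoms per frame.
#'
#' @param series A [coord_series()].
#' @param selection Selection(s) to accumulate.
#' @param spacing Voxel edge, Angstrom (default 0.5).
#' @param align Selection name(s) used for the superposition (needs >= 3
#'   non-collinear points); `NULL` disables alignment.
#' @param reference_frame Frame aligned onto (default: first frame).
#' @return A `density_grid` tibble: voxel indices `ix, iy, iz`, centres
#'   `x, y, z`, `count`, `density` (per Angstrom^3), with attributes
#'   `origin`, `spacing`, `n_frames`, `selection`.
#' @export
density_map <- function(series, selection, spacing = 0.5, align = NULL,
                        reference_frame = NULL) {
  stopifnot(spacing > 0)
  frames <- sort(unique(series$frame))
  reference_frame <- reference_frame %||% frames[1]
  sel_rows <- series[series$selection %in% selection, , drop = FALSE]
  if (nrow(sel_rows) == 0L) abort("selection not found in series")
  if (!is.null(align)) {
    ref_rows <- series[series$frame == reference_frame &
                         series$selection %in% align, , drop = FALSE]
    ref_rows <- ref_rows[order(ref_rows$selection), , drop = FALSE]
    q <- as.matrix(ref_rows[, c("x", "y", "z")])
    if (nrow(q) < 3L || qr(sweep(q, 2, colMeans(q)))$rank < 2L) {
      abort("alignment selection needs >= 3 non-collinear points")
    }
    pieces <- lapply(frames, function(f) {
      a_rows <- series[series$frame == f & series$selection %in% align, ,
                       drop = FALSE]
      a_rows <- a_rows[order(a_rows$selection), , drop = FALSE]
      if (nrow(a_rows) != nrow(q)) {
        abort(paste0("alignment selection incomplete in frame ", f))
      }
      fit <- kabsch(as.matrix(a_rows[, c("x", "y", "z")]), q)
      s_rows <- sel_rows[sel_rows$frame == f, , drop = FALSE]
      apply_rigid(as.matrix(s_rows[, c("x", "y", "z")]), fit)
    })
    xyz <- do.call(rbind, pieces)
  } else {
    xyz <- as.matrix(sel_rows[, c("x", "y", "z")])
  }
  n_frames <- length(frames)
  origin <- floor(apply(xyz, 2, min) / spacing) * spacing
  idx <- floor(sweep(xyz, 2, origin) / spacing)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  tab <- table(key)
  ids <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  ids <- matrix(as.integer(ids), ncol = 3)
  out <- tibble(
    ix = ids[, 1], iy = ids[, 2], iz = ids[, 3],
    x = origin[1] + (ids[, 1] + 0.5) * spacing,
    y = origin[2] + (ids[, 2] + 0.5) * spacing,
    z = origin[3] + (ids[, 3] + 0.5) * spacing,
    count = as.integer(tab),
    density = as.integer(tab) / (n_frames * spacing^3)
  )
  attr(out, "origin") <- origin
  attr(out, "spacing") <- spacing
  attr(out, "n_frames") <- n_frames
  attr(out, "selection") <- selection
  class(out) <- c("density_grid", class(out))
  out
}

#' Write a density grid as delimited text
#'
#' Voxel table (`ix iy iz x y z count density`) with grid metadata in
#' `#`-prefixed header lines; trivially convertible to standard volumetric
#' formats.
#'
#' @param grid A `density_grid`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_density_grid <- function(grid, file) {
  stopifnot(inherits(grid, "density_grid"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# origin ", paste(attr(grid, "origin"), collapse = " ")),
    paste0("# spacing ", attr(grid, "spacing")),
    paste0("# n_frames ", attr(grid, "n_frames"))
  ), con)
  utils::write.table(as.data.frame(grid), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Detect a step (escape event) in a distance series
#'
#' First frame at which the distance exceeds `threshold` and stays above
#' it for `persistence` consecutive frames — the signature of a ligand or
#' ion leaving its binding site.
#'
#' @param ds A `distance_series`.
#' @param threshold Angstrom (default 5).
#' @param persistence Frames the excursion must persist (default 5).
#' @return The frame number, or `NA` if no escape is detected.
#' @export
detect_escape <- function(ds, threshold = 5, persistence = 5) {
  above <- ds$distance > threshold
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= persistence) return(ds$frame[i - persistence + 1L])
  }
  NA_integer_
}
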