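# Cache for dipolar kernel matrices and Gauss-Legendre node sets
.deer_cache <- new.env(parent = emptyenv())

#' Dipolar kernel of the four-pulse DEER experiment
#'
#' `K(t, r) = int_0^1 cos[(1 - 3 x^2) w_dd t] dx` with
#' `w_dd = 2 pi * 52.04 / r^3` (rad/us for `r` in nm), the powder-averaged
#' dipolar modulation of two spin labels a distance `r` apart. Evaluated by
#' Gauss-Legendre quadrature whose order grows with the maximum accumulated
#' phase, so columns are accurate to better than 1e-8 across the default
#' 1-8 nm grid. `K(0, r) = 1` exactly.
#'
#' @param t Time grid, microseconds (from 0).
#' @param r Distance grid, nm; all > 0.
#' @return A `length(t)` by `length(r)` kernel matrix.
#' @examples
#' K <- dipolar_kernel(seq(0, 2, 0.05), seq(2, 5, 0.5))
#' K[1, ]  # all 1 at t = 0
#' @export
dipolar_kernel <- function(t, r) {
  t <- as.numeric(t)
  r <- as.numeric(r)
  if (any(r <= 0)) abort("all distances must be positive")
  key <- digest::digest(list(t, r))
  hit <- .deer_cache[[key]]
  if (!is.null(hit)) return(hit)
  omega <- 2 * pi * 52.04 / r^3
  tmax <- max(abs(t))
  phase <- 3 * omega * tmax
  buckets <- c(48, 96, 192, 384, 768, 1536, 3072, 6144)
  need <- pmax(48, ceiling(0.7 * phase + 40))
  bucket <- vapply(need, function(m) buckets[which(buckets >= m)[1]],
                   numeric(1))
  if (any(is.na(bucket))) {
    abort("time/distance grid requires an unreasonably fine quadrature; \
shorten the trace or raise the minimum distance")
  }
  K <- matrix(0, length(t), length(r))
  for (b in unique(bucket)) {
    gl <- .deer_cache[[paste0("gl", b)]]
    if (is.null(gl)) {
      gl <- pracma::gaussLegendre(b, 0, 1)
      .deer_cache[[paste0("gl", b)]] <- gl
    }
    cols <- which(bucket == b)
    M <- t %o% omega[cols]
    acc <- matrix(0, length(t), length(cols))
    for (k in seq_len(b)) {
      acc <- acc + gl$w[k] * cos(M * (1 - 3 * gl$x[k]^2))
    }
    K[, cols] <- acc
  }
  .deer_cache[[key]] <- K
  K
}

#' Gaussian-mixture model of a DEER distance distribution
#'
#' Describes a trace as a background-multiplied dipolar signal whose
#' distance distribution `P(r)` is a sum of Gaussian components:
#' `V(t) = B(t) [1 - depth + depth * int K(t, r) P(r) dr]` with stretched-
#' exponential background `B(t) = exp(-k t^(d/3))` (dimension `d = 3` for a
#' homogeneous 3-D spin bath).
#'
#' @param components Data frame with columns `mean` (nm), `width` (nm, > 0),
#'   `weight` (summing to 1).
#' @param depth Modulation depth in (0, 1).
#' @param bg_k Background decay rate (>= 0, per us^(d/3)).
#' @param bg_d Background dimensionality (default 3).
#' @return A `deer_model`.
#' @examples
#' deer_model(data.frame(mean = c(3, 4.5), width = 0.3,
#'                       weight = c(0.7, 0.3)))
#' @export
deer_model <- function(components, depth = 0.3, bg_k = 0.05, bg_d = 3) {
  components <- as_tibble(components)
  stopifnot(all(c("mean", "width", "weight") %in% names(components)),
            nrow(components) >= 1L)
  if (any(components$width <= 0)) abort("component widths must be positive")
  if (abs(sum(components$weight) - 1) > 1e-8) {
    abort("component weights must sum to 1")
  }
  if (depth <= 0 || depth >= 1) abort("modulation depth must be in (0, 1)")
  if (bg_k < 0) abort("background rate must be >= 0")
  structure(list(components = components[order(components$mean), ],
                 depth = depth, bg_k = bg_k, bg_d = bg_d,
                 param = NULL, condition = NULL),
            class = "deer_model")
}

#' @export
print.deer_model <- function(x, ...) {
  cat("<deer_model> ", nrow(x$components), " component(s), depth ",
      signif(x$depth, 3), ", background k ", signif(x$bg_k, 3),
      if (!is.null(x$condition)) paste0(" [", x$condition, "]"), "\n",
      sep = "")
  print(x$components)
  invisible(x)
}

# P(r) of a model on a grid, trapezoid-normalized
model_pr <- function(model, r_grid) {
  mixture_pr(model$components$mean, model$components$width,
             model$components$weight, r_grid)
}

mixture_pr <- function(means, widths, weights, r_grid) {
  p <- rep(0, length(r_grid))
  for (k in seq_along(means)) {
    p <- p + weights[k] * dnorm(r_grid, means[k], widths[k])
  }
  z <- trapz_integral(r_grid, p)
  if (z <= 0) return(p)
  p / z
}

# Forward signal V(t) for parameter pieces; kernel is K(t, r) on r_grid
deer_signal <- function(p_r, kernel, r_grid, t, depth, bg_k, bg_d) {
  s <- as.numeric(kernel %*% (p_r * trapezoid_weights(r_grid)))
  exp(-bg_k * t^(bg_d / 3)) * (1 - depth + depth * s)
}

#' Simulate a DEER time trace
#'
#' Forward-evaluates a [deer_model()] on a time grid and adds Gaussian
#' noise: the synthetic-data stand-in for the spectrometer. `V(0) = 1`
#' before noise.
#'
#' @param model A [deer_model()].
#' @param t Time grid, microseconds.
#' @param noise Gaussian noise standard deviation.
#' @param seed Integer seed (bit-identical trace on rerun).
#' @param condition Condition label stored on the trace.
#' @param r_grid Distance grid for the forward integral.
#' @return A `deer_trace` tibble with columns `time`, `amplitude` and
#'   attributes `condition`, `noise`, `truth` (the generating model).
#' @export
simulate_trace <- function(model, t = seq(0, 2.5, by = 0.01), noise = 0,
                           seed = NULL, condition = "sim",
                           r_grid = seq(1, 8, by = 0.02)) {
  stopifnot(inherits(model, "deer_model"), all(diff(t) > 0), t[1] >= 0,
            noise >= 0)
  K <- dipolar_kernel(t, r_grid)
  v <- deer_signal(model_pr(model, r_grid), K, r_grid, t, model$depth,
                   model$bg_k, model$bg_d)
  v <- v + with_seed(seed, rnorm(length(t), 0, noise))
  out <- tibble(time = t, amplitude = v)
  attr(out, "condition") <- condition
  attr(out, "noise") <- noise
  attr(out, "truth") <- model
  class(out) <- c("deer_trace", class(out))
  out
}

#' Read a DEER trace from two-column delimited text
#'
#' @param file Path; two numeric columns (time in microseconds, normalized
#'   echo amplitude), whitespace/comma/tab delimited, `#` comments allowed.
#' @param condition Condition label.
#' @return A `deer_trace` tibble.
#' @export
read_deer_trace <- function(file, condition = basename(file)) {
  raw <- utils::read.table(file, header = FALSE, comment.char = "#",
                           sep = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) {
    raw <- utils::read.table(file, header = FALSE, sep = ",",
                             comment.char = "#")
  }
  out <- tibble(time = as.numeric(raw[[1]]), amplitude = as.numeric(raw[[2]]))
  if (any(diff(out$time) <= 0)) abort("time grid must be strictly increasing")
  attr(out, "condition") <- condition
  class(out) <- c("deer_trace", class(out))
  out
}

# Normalize fit input to a named list of traces
as_trace_list <- function(traces) {
  if (inherits(traces, "deer_trace")) traces <- list(traces)
  stopifnot(is.list(traces), length(traces) >= 1L)
  nms <- names(traces)
  auto <- vapply(seq_along(traces), function(i) {
    attr(traces[[i]], "condition") %||% paste0("condition", i)
  }, character(1))
  if (is.null(nms)) nms <- auto
  nms[nms == ""] <- auto[nms == ""]
  names(traces) <- make.unique(nms)
  traces
}

# ---- parameter packing ---------------------------------------------------
# theta layout: mu[1..K], log sigma (K, or K*C when widths are free per
# condition), then per condition: (K-1) weight logits, logit depth, log k.
deer_par_map <- function(k, n_cond, share_widths) {
  n_sg <- if (share_widths) k else k * n_cond
  per_cond <- (k - 1) + 2
  list(k = k, n_cond = n_cond, share_widths = share_widths,
       i_mu = seq_len(k), i_sg = k + seq_len(n_sg),
       off_cond = k + n_sg + (seq_len(n_cond) - 1) * per_cond,
       per_cond = per_cond,
       n_par = k + n_sg + n_cond * per_cond)
}

deer_unpack <- function(theta, map, cond_idx) {
  k <- map$k
  mu <- theta[map$i_mu]
  sg <- exp(theta[map$i_sg])
  if (!map$share_widths) {
    sg <- sg[(cond_idx - 1) * k + seq_len(k)]
  }
  off <- map$off_cond[cond_idx]
  if (k > 1) {
    logits <- c(theta[off + seq_len(k - 1)], 0)
    w <- exp(logits - max(logits))
    w <- w / sum(w)
  } else {
    w <- 1
  }
  depth <- stats::plogis(theta[off + (k - 1) + 1])
  bg_k <- exp(theta[off + (k - 1) + 2])
  list(mu = mu, sg = sg, w = w, depth = depth, bg_k = bg_k)
}

deer_residuals <- function(theta, map, cond_data, r_grid, bg_d) {
  unlist(lapply(seq_along(cond_data), function(ci) {
    d <- cond_data[[ci]]
    p <- deer_unpack(theta, map, ci)
    pr <- mixture_pr(p$mu, p$sg, p$w, r_grid)
    deer_signal(pr, d$kernel, r_grid, d$t, p$depth, p$bg_k, bg_d) - d$obs
  }), use.names = FALSE)
}

deer_bounds <- function(map, r_grid) {
  lo <- rep(-Inf, map$n_par)
  hi <- rep(Inf, map$n_par)
  lo[map$i_mu] <- min(r_grid) + 0.2
  hi[map$i_mu] <- max(r_grid) - 0.2
  lo[map$i_sg] <- log(0.015)
  hi[map$i_sg] <- log(1.5)
  for (off in map$off_cond) {
    idx <- off + seq_len(map$per_cond)
    lo[idx] <- c(rep(-8, map$k - 1), -6, log(1e-5))
    hi[idx] <- c(rep(8, map$k - 1), 6, log(5))
  }
  list(lower = lo, upper = hi)
}

deer_starts <- function(k, map, r_grid, n_starts) {
  span <- range(r_grid) + c(0.5, -0.5) * diff(range(r_grid)) * 0.25
  base_mu <- seq(2.5, 5.5, length.out = max(k, 2))[seq_len(k)]
  if (k == 1) base_mu <- 3.5
  lapply(seq_len(n_starts), function(s) {
    mu <- base_mu
    if (s > 1) mu <- sort(pmin(pmax(mu + rnorm(k, 0, 0.5), span[1]), span[2]))
    theta <- numeric(map$n_par)
    theta[map$i_mu] <- mu
    theta[map$i_sg] <- log(0.3)
    for (off in map$off_cond) {
      theta[off + seq_len(map$per_cond)] <-
        c(rep(0, k - 1), stats::qlogis(0.3), log(0.1))
    }
    theta
  })
}

#' Fit sums of Gaussian distance components to DEER traces
#'
#' Global nonlinear least squares across one or more conditions: component
#' means (and, by default, widths) are shared between conditions while
#' weights, modulation depth and background are condition-specific, so
#' ion-induced changes appear as a reweighting of short- and long-distance
#' components. The number of components is scanned from 1 to
#' `max_components` and selected by the Bayesian information criterion;
#' each count is fitted from multiple starting points with
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]).
#'
#' @param traces A `deer_trace` or (named) list of them, one per condition.
#' @param max_components Largest component count scanned (>= 1).
#' @param r_grid Distance grid, nm.
#' @param seed Integer seed (multistart jitter; fixed seed gives an
#'   identical selected model).
#' @param share_widths Share component widths across conditions (default)
#'   or free them per condition.
#' @param n_starts Starting points per component count.
#' @param bg_d Background dimensionality.
#' @return A `deer_fit`: per-condition [deer_model()]s with parameter
#'   covariance (`$models`), 2-sigma distance distributions
#'   (`$distributions`, see [confidence_band()]), the model-selection table
#'   (`$selection`), `$selected_k`, and fitted curves (`$fitted`).
#' @examples
#' truth <- deer_model(data.frame(mean = 3.5, width = 0.25, weight = 1))
#' tr <- simulate_trace(truth, seq(0, 1.5, 0.015), noise = 0.003, seed = 2)
#' fit <- fit_mixture(tr, max_components = 2, seed = 1)
#' tidy(fit)
#' @export
fit_mixture <- function(traces, max_components = 3,
                        r_grid = seq(1, 8, by = 0.02), seed = 1,
                        share_widths = TRUE, n_starts = 3, bg_d = 3) {
  stopifnot(max_components >= 1)
  traces <- as_trace_list(traces)
  n_cond <- length(traces)
  cond_data <- lapply(traces, function(tr) {
    list(t = tr$time, obs = tr$amplitude,
         kernel = dipolar_kernel(tr$time, r_grid))
  })
  n_obs <- sum(vapply(cond_data, function(d) length(d$obs), numeric(1)))

  scan <- vector("list", max_components)
  with_seed(seed, for (k in seq_len(max_components)) {
    map <- deer_par_map(k, n_cond, share_widths)
    bounds <- deer_bounds(map, r_grid)
    starts <- deer_starts(k, map, r_grid, n_starts)
    if (k > 1L && !is.null(scan[[k - 1L]])) {
      starts <- c(starts,
                  deer_warm_starts(scan[[k - 1L]]$theta, scan[[k - 1L]]$map,
                                   map, r_grid))
    }
    best <- NULL
    diag_msgs <- character(0)
    for (theta0 in starts) {
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = theta0,
          fn = deer_residuals, map = map, cond_data = cond_data,
          r_grid = r_grid, bg_d = bg_d,
          lower = bounds$lower, upper = bounds$upper,
          control = minpack.lm::nls.lm.control(maxiter = 300)
        ),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        diag_msgs <- c(diag_msgs, conditionMessage(fit))
        next
      }
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(theta = fit$par, rss = rss, info = fit$info,
                     message = fit$message)
      }
    }
    if (is.null(best)) {
      abort(paste0("no start converged for ", k, " component(s): ",
                   paste(diag_msgs, collapse = "; ")))
    }
    best$map <- map
    best$k <- k
    best$bic <- n_obs * log(best$rss / n_obs) + map$n_par * log(n_obs)
    scan[[k]] <- best
  })

  selection <- purrr::map_dfr(scan, function(s) {
    tibble(k = s$k, n_par = s$map$n_par, rss = s$rss, bic = s$bic,
           converged = s$info %in% 1:4)
  })
  sel <- scan[[which.min(selection$bic)]]
  map <- sel$map
  theta <- sel$theta

  # order components by ascending mean (permute weights/widths consistently)
  ord <- order(theta[map$i_mu])
  theta <- deer_reorder(theta, map, ord)

  cov <- deer_covariance(theta, map, cond_data, r_grid, bg_d, sel$rss, n_obs)

  models <- purrr::imap(cond_data, function(d, cond) {
    ci <- match(cond, names(cond_data))
    p <- deer_unpack(theta, map, ci)
    m <- deer_model(tibble(mean = p$mu, width = p$sg,
                           weight = as.numeric(p$w)),
                    depth = p$depth, bg_k = p$bg_k, bg_d = bg_d)
    m$condition <- cond
    m$param <- list(theta = theta, cov = cov, map = map, cond_idx = ci)
    m
  })
  fitted <- purrr::imap_dfr(cond_data, function(d, cond) {
    ci <- match(cond, names(cond_data))
    p <- deer_unpack(theta, map, ci)
    pr <- mixture_pr(p$mu, p$sg, p$w, r_grid)
    tibble(condition = cond, time = d$t, observed = d$obs,
           fitted = deer_signal(pr, d$kernel, r_grid, d$t, p$depth, p$bg_k,
                                bg_d))
  })
  dists <- purrr::map(models, confidence_band, r_grid = r_grid)
  structure(
    list(models = models, distributions = dists, selection = selection,
         selected_k = sel$k, fitted = fitted, r_grid = r_grid, seed = seed,
         share_widths = share_widths),
    class = "deer_fit"
  )
}

# Warm starts for a k-component fit from the best (k-1)-component solution:
# keep its means/widths and per-condition weights, insert the new component
# at several candidate positions with a small initial weight.
deer_warm_starts <- function(prev_theta, prev_map, map, r_grid) {
  k_prev <- prev_map$k
  k <- map$k
  mu_prev <- prev_theta[prev_map$i_mu]
  lo <- min(r_grid) + 0.3
  hi <- max(r_grid) - 0.3
  cand <- unique(pmin(pmax(c(mu_prev + 1.2, mu_prev - 1.2,
                             mu_prev + 0.7, mu_prev - 0.7,
                             mean(range(r_grid))), lo), hi))
  lapply(cand, function(m_new) {
    theta <- numeric(map$n_par)
    theta[map$i_mu] <- c(mu_prev, m_new)
    if (map$share_widths) {
      theta[map$i_sg] <- c(prev_theta[prev_map$i_sg], log(0.3))
    } else {
      for (c in seq_len(map$n_cond)) {
        prev_idx <- prev_map$i_sg[(c - 1) * k_prev + seq_len(k_prev)]
        theta[map$i_sg[(c - 1) * k + seq_len(k)]] <-
          c(prev_theta[prev_idx], log(0.3))
      }
    }
    for (c in seq_len(map$n_cond)) {
      prev_off <- prev_map$off_cond[c]
      logits_prev <- c(prev_theta[prev_off + seq_len(k_prev - 1)], 0)
      w_prev <- exp(logits_prev - max(logits_prev))
      w_prev <- w_prev / sum(w_prev)
      w <- c(0.85 * w_prev, 0.15)
      off <- map$off_cond[c]
      theta[off + seq_len(k - 1)] <-
        pmin(pmax(log(w[seq_len(k - 1)] / w[k]), -8), 8)
      theta[off + (k - 1) + 1:2] <-
        prev_theta[prev_off + (k_prev - 1) + 1:2]
    }
    theta
  })
}

deer_reorder <- function(theta, map, ord) {
  k <- map$k
  if (k == 1 || identical(ord, seq_len(k))) return(theta)
  out <- theta
  out[map$i_mu] <- theta[map$i_mu][ord]
  if (map$share_widths) {
    out[map$i_sg] <- theta[map$i_sg][ord]
  } else {
    for (c in seq_len(map$n_cond)) {
      idx <- map$i_sg[(c - 1) * k + seq_len(k)]
      out[idx] <- theta[idx][ord]
    }
  }
  for (off in map$off_cond) {
    logits <- c(theta[off + seq_len(k - 1)], 0)[ord]
    out[off + seq_len(k - 1)] <- logits[seq_len(k - 1)] - logits[k]
  }
  out
}

deer_covariance <- function(theta, map, cond_data, r_grid, bg_d, rss,
                            n_obs) {
  J <- pracma::jacobian(function(th) {
    deer_residuals(th, map, cond_data, r_grid, bg_d)
  }, theta)
  dof <- max(n_obs - map$n_par, 1)
  sigma2 <- rss / dof
  jtj <- crossprod(J)
  cov <- tryCatch(sigma2 * solve(jtj), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(cov))) {
    warn("singular parameter covariance; band widened by ridge correction")
    cov <- sigma2 * solve(jtj + diag(1e-8 * max(diag(jtj)), nrow(jtj)))
  }
  cov
}

#' @export
print.deer_fit <- function(x, ...) {
  cat("<deer_fit> ", length(x$models), " condition(s); selected ",
      x$selected_k, " component(s)\n", sep = "")
  print(x$selection)
  for (m in x$models) print(m)
  invisible(x)
}

#' Distance distribution with a pointwise 2-sigma confidence band
#'
#' Propagates the fitted parameter covariance through `P(r)` to first
#' order (delta method), reporting the band at 2 sigma (95%). The band is
#' truncated at zero (densities cannot be negative) and always contains
#' the best-fit curve. A model without covariance (e.g. hand-built) yields
#' a zero-width band.
#'
#' @param model A `deer_model` (typically from [fit_mixture()], which
#'   attaches the covariance) or a `deer_fit` (band of every condition,
#'   returned as a named list).
#' @param r_grid Distance grid, nm.
#' @return A `distance_distribution` tibble: `r`, `p`, `lower`, `upper`,
#'   with `p` integrating to 1 (trapezoid rule).
#' @export
confidence_band <- function(model, r_grid = seq(1, 8, by = 0.02)) {
  if (inherits(model, "deer_fit")) {
    return(purrr::map(model$models, confidence_band, r_grid = r_grid))
  }
  stopifnot(inherits(model, "deer_model"))
  p <- model_pr(model, r_grid)
  if (is.null(model$param) || all(model$param$cov == 0)) {
    band <- rep(0, length(r_grid))
  } else {
    pm <- model$param
    p_fun <- function(th) {
      u <- deer_unpack(th, pm$map, pm$cond_idx)
      mixture_pr(u$mu, u$sg, u$w, r_grid)
    }
    J <- pracma::jacobian(p_fun, pm$theta)
    band <- 2 * sqrt(pmax(rowSums((J %*% pm$cov) * J), 0))
  }
  out <- tibble(r = r_grid, p = p, lower = pmax(p - band, 0),
                upper = p + band)
  attr(out, "condition") <- model$condition
  class(out) <- c("distance_distribution", class(out))
  out
}

#' Summary statistics of a distance distribution
#'
#' @param dist A `distance_distribution`.
#' @return A one-row tibble: mean distance, mode, integral.
#' @export
distribution_stats <- function(dist) {
  stopifnot(inherits(dist, "distance_distribution"))
  tibble(
    mean = trapz_integral(dist$r, dist$r * dist$p),
    mode = dist$r[which.max(dist$p)],
    integral = trapz_integral(dist$r, dist$p)
  )
}
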