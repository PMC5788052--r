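#' Settings for the predicted error density
#'
#' @description
#' The population-coding model predicts the distribution of recall errors as a
#' mixture over the total spike count `N ~ Poisson(lambda)`:
#' a uniform component for `N = 0` (nothing decodable) plus, for each `n >= 1`,
#' the density `f_n` of the resultant direction of `n` independent von Mises
#' spike labels — the dense-population limit in which each spike's preferred
#' value is a von Mises draw around the stimulus. `density_settings()` controls
#' how that mixture is evaluated.
#'
#' Two evaluation methods are available. `"quadrature"` (default, used for
#' fitting) is deterministic: `f_1` is the von Mises density itself, `f_2` is
#' an exact one-dimensional quadrature (by tilting the two-step uniform random
#' walk), `f_n` for `3 <= n <= n_table` is a renormalized two-dimensional
#' saddlepoint approximation integrated radially, tabulated once per session
#' on a logarithmic concentration grid and interpolated, and larger `n` use
#' the asymptotic von Mises limit `VM(0, n * kappa * A(kappa))`. `"mc"` is the
#' brute-force per-`n` Monte Carlo estimate (seeded, histogrammed on the same
#' grid); it is slower and noisy but makes no analytic approximation, and
#' serves as the independent cross-check of the quadrature path.
#'
#' @param step_deg Grid resolution in degrees of internal angle (default 1).
#' @param method `"quadrature"` or `"mc"`.
#' @param n_table Largest spike count covered by the saddlepoint table
#'   (default 40); larger counts use the asymptotic limit.
#' @param truncation Poisson tail mass at which the mixture is truncated
#'   (default `1e-6`).
#' @param n_cap Largest admissible truncation point. A gain so large that the
#'   truncated sum would need more than `n_cap` components is a settings
#'   error.
#' @param kappa_range,kappa_points Range and size of the logarithmic
#'   concentration grid backing the saddlepoint table.
#' @param n_draws Monte Carlo draws per retained spike count
#'   (`method = "mc"` only; default 50000).
#' @param seed Seed for the Monte Carlo method (ignored by quadrature).
#' @param floor Per-trial likelihood floor guarding numerical underflow in
#'   extreme tails (default `1e-10`).
#' @return A list of class `density_settings`.
#' @export
density_settings <- function(step_deg = 1, method = c("quadrature", "mc"),
                             n_table = 40L, truncation = 1e-6, n_cap = 5000L,
                             kappa_range = c(log(2) / 2 + 1e-9, 400),
                             kappa_points = 176L, n_draws = 50000L,
                             seed = 1L, floor = 1e-10) {
  method <- match.arg(method)
  stopifnot(step_deg > 0, truncation > 0, truncation < 1e-2,
            n_table >= 3, n_cap > n_table, floor > 0)
  structure(list(step_deg = step_deg, method = method,
                 n_table = as.integer(n_table), truncation = truncation,
                 n_cap = as.integer(n_cap), kappa_range = kappa_range,
                 kappa_points = as.integer(kappa_points),
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 floor = floor),
            class = "density_settings")
}

# ---- resultant-direction component densities f_n ---------------------------

# Exact f_2 on a half-grid of angles in [0, pi]:
#   f_2(phi) = (2 pi^2 I0(k)^2)^{-1} int_0^pi exp(2 k cos(v/2) cos(phi)) dv
# (v is the angle between the two spike labels; tilting the uniform two-step
# walk by exp(kappa * R * cos(phi)) makes v uniform on (0, pi)).
f2_exact_half <- function(kappa, cosphi, nq = 256L) {
  v <- (seq_len(nq) - 0.5) * pi / nq
  rr <- 2 * cos(v / 2)
  lc <- -log(2 * pi^2) - 2 * log_bessel_I0(kappa)
  M <- kappa * outer(rr, cosphi)
  cm <- col_maxs(M)
  exp(lc + cm) * .colSums(exp(sweep(M, 2, cm)), nq, length(cosphi)) * (pi / nq)
}

# Renormalized saddlepoint f_n (n >= 3) on a half-grid. The 2-D saddlepoint
# density of the summed spike-label vector is integrated radially with the
# substitution omega = A^{-1}(r/n) (omega is the tilted concentration), which
# keeps the integrand resolved for all kappa:
#   f_n(phi) ~ int (n/2pi) sqrt(omega A A') exp(psi) domega,
#   psi = n[log I0(omega) - log I0(kappa)] - n A(omega) omega
#         + kappa n A(omega) cos(phi).
fn_saddle_half <- function(n, kappa, cosphi, n_omega = 240L) {
  sd_om <- 1 / sqrt(n * max(vm_A_prime(kappa), 1e-12))
  om_hi <- kappa + 10 * sd_om + 3 * kappa
  om_lo <- min(0.005, kappa * 1e-3)
  om <- exp(seq(log(om_lo), log(om_hi), length.out = n_omega))
  a <- vm_A(om)
  ap <- vm_A_prime(om)
  base <- n * (log_bessel_I0(om) - log_bessel_I0(kappa)) - n * a * om
  pref <- log(n / (2 * pi)) + 0.5 * log(om * a * ap)
  w <- c(diff(om) / 2, 0) + c(0, diff(om) / 2)
  M <- (base + pref + log(w)) + (kappa * n) * outer(a, cosphi)
  cm <- col_maxs(M)
  f <- exp(cm - max(cm)) * .colSums(exp(sweep(M, 2, cm)), n_omega, length(cosphi))
  f / half_grid_integral(f, cosphi)   # renormalize on the circle
}

# integral over the full circle of a symmetric density given on the half grid
# phi = 0, step, ..., pi (trapezoid, doubled)
half_grid_integral <- function(f, cosphi) {
  np <- length(cosphi)
  step <- pi / (np - 1)
  2 * (sum(f) - (f[1] + f[np]) / 2) * step
}

col_maxs <- function(M) {
  tM <- t(M)
  tM[cbind(seq_len(nrow(tM)), max.col(tM, ties.method = "first"))]
}

# ---- session table of f_n slices over a log-kappa grid ---------------------

saddle_table <- function(settings) {
  key <- paste0("tab_", settings$step_deg, "_", settings$n_table, "_",
                settings$kappa_points, "_",
                paste(signif(settings$kappa_range, 10), collapse = "_"))
  if (!is.null(the[[key]])) return(the[[key]])
  phi <- seq(0, pi, by = settings$step_deg * pi / 180)
  cosphi <- cos(phi)
  lk <- seq(log(settings$kappa_range[1]), log(settings$kappa_range[2]),
            length.out = settings$kappa_points)
  ns <- 2:settings$n_table
  F <- array(NA_real_, dim = c(length(lk), length(ns), length(phi)))
  for (i in seq_along(lk)) {
    kap <- exp(lk[i])
    F[i, 1, ] <- f2_exact_half(kap, cosphi)
    for (j in seq_along(ns)[-1]) {
      F[i, j, ] <- fn_saddle_half(ns[j], kap, cosphi)
    }
  }
  tab <- list(log_kappa = lk, ns = ns, phi = phi, F = F)
  the[[key]] <- tab
  tab
}

# ---- the mixture over Poisson spike counts ---------------------------------

# Density of the decoded error on the half grid [0, pi] for a given population
# gain and tuning concentration (quadrature method).
pop_density_half <- function(lambda, kappa, settings) {
  tab <- saddle_table(settings)
  phi <- tab$phi
  np <- length(phi)
  if (lambda <= 0) return(rep(1 / (2 * pi), np))
  n_hi <- qpois(settings$truncation, lambda, lower.tail = FALSE)
  if (n_hi > settings$n_cap) {
    abort(sprintf(
      "population gain %.3g needs %d mixture components (cap %d); raise n_cap in density_settings()",
      lambda, n_hi, settings$n_cap), class = "retropop_gain_cap")
  }
  kap <- min(max(kappa, exp(tab$log_kappa[1])), exp(tab$log_kappa[length(tab$log_kappa)]))
  wts <- dpois(0:n_hi, lambda)
  wts <- wts / sum(wts)
  dens <- wts[1] / (2 * pi) * rep(1, np)
  if (n_hi >= 1) dens <- dens + wts[2] * vm_pdf(phi, kap)
  n_tab_hi <- min(n_hi, settings$n_table)
  if (n_tab_hi >= 2) {
    # interpolate table slices linearly in log kappa
    lk <- tab$log_kappa
    x <- log(kap)
    i <- findInterval(x, lk, all.inside = TRUE)
    t <- (x - lk[i]) / (lk[i + 1] - lk[i])
    idx <- seq_len(n_tab_hi - 1)          # rows of tab$F for n = 2..n_tab_hi
    w_n <- wts[idx + 2]                   # Poisson weights for those n
    slice <- (1 - t) * F_rows(tab, i, idx) + t * F_rows(tab, i + 1, idx)
    dens <- dens + as.vector(crossprod(w_n, slice))
  }
  if (n_hi > settings$n_table) {
    # asymptotic von Mises components VM(0, n * kappa * A(kappa)); bucket the
    # Poisson mass if many counts are retained
    ns <- (settings$n_table + 1):n_hi
    w <- wts[ns + 1]
    if (length(ns) > 64) {
      br <- unique(round(seq(1, length(ns), length.out = 65)))
      grp <- findInterval(seq_along(ns), br, rightmost.closed = TRUE)
      w_g <- tapply(w, grp, sum)
      n_g <- tapply(w * ns, grp, sum) / pmax(w_g, 1e-300)
      keep <- w_g > 1e-12
      ns <- n_g[keep]; w <- w_g[keep]
    }
    ka <- kap * vm_A(kap)
    for (m in seq_along(ns)) dens <- dens + w[m] * vm_pdf(phi, ns[m] * ka)
  }
  dens / half_grid_integral(dens, cos(phi))
}

# matrix of table slices: rows = selected n indices, cols = phi
F_rows <- function(tab, ik, idx) {
  matrix(tab$F[ik, idx, ], nrow = length(idx))
}

# Monte Carlo version of pop_density_half: per-n resultant simulation,
# histogrammed on the (full) grid and folded to the half grid.
pop_density_half_mc <- function(lambda, kappa, settings) {
  phi <- seq(0, pi, by = settings$step_deg * pi / 180)
  np <- length(phi)
  if (lambda <= 0) return(rep(1 / (2 * pi), np))
  n_hi <- qpois(settings$truncation, lambda, lower.tail = FALSE)
  if (n_hi > min(settings$n_cap, 500)) {
    abort(sprintf("population gain %.3g too large for the Monte Carlo method (needs %d components)",
                  lambda, n_hi), class = "retropop_gain_cap")
  }
  wts <- dpois(0:n_hi, lambda)
  wts <- wts / sum(wts)
  step <- settings$step_deg * pi / 180
  breaks <- seq(-step / 2, pi + step / 2, by = step)   # folded |error| bins
  dens <- wts[1] / (2 * pi) * rep(1, np)
  nd <- settings$n_draws
  withr::with_seed(settings$seed, {
    for (n in seq_len(n_hi)) {
      if (wts[n + 1] < 1e-12) next
      th <- matrix(rvonmises(n * nd, kappa), nrow = n)
      d <- abs(atan2(.colSums(sin(th), n, nd), .colSums(cos(th), n, nd)))
      cnt <- tabulate(findInterval(d, breaks, all.inside = TRUE), np)
      # fold: interior bins of |d| carry both signs; the end bins half-width
      w_bin <- c(step / 2, rep(step, np - 2), step / 2) * 2
      dens <- dens + wts[n + 1] * cnt / (nd * w_bin)
    }
  })
  dens / half_grid_integral(dens, cos(phi))
}

#' Predicted error density of the population-coding model
#'
#' Tabulates the model-predicted density of recall errors
#' (`estimate - stimulus`) on an even circular grid. The density depends on
#' the parameters only through the population gain [pop_gain()] and the tuning
#' concentration; swap and guess probabilities are *not* mixed in here (they
#' enter the trial likelihood, [popmodel_loglik()]).
#'
#' Results are cached per session by gain, concentration and settings.
#'
#' @param params A [pop_params()] object.
#' @param settings A [density_settings()] object.
#' @return A tibble of class `rc_density` with columns `error` (radians,
#'   strictly increasing, covering `[-pi, pi)`) and `density`; parameters and
#'   settings are attached as attributes. The trapezoidal circular integral
#'   is 1 within `1e-3` and the density is symmetric about 0.
#' @examples
#' d <- error_density(pop_params(rmax = 15, fwhm = 1.25))
#' @export
error_density <- function(params, settings = density_settings()) {
  stopifnot(inherits(params, "pop_params"), inherits(settings, "density_settings"))
  lambda <- pop_gain(params)
  kappa <- params$kappa
  key <- paste0("dens_", settings$method, "_", signif(lambda, 12), "_",
                signif(kappa, 12), "_", settings$step_deg, "_",
                settings$n_draws, "_", settings$seed)
  half <- the[[key]]
  if (is.null(half)) {
    half <- switch(settings$method,
      quadrature = pop_density_half(lambda, kappa, settings),
      mc = pop_density_half_mc(lambda, kappa, settings))
    the[[key]] <- half
  }
  step <- settings$step_deg * pi / 180
  grid <- seq(-pi, pi - step, by = step)
  dens <- half[round(abs(grid) / step) + 1L]
  out <- tibble::tibble(error = grid, density = dens)
  class(out) <- c("rc_density", class(out))
  attr(out, "params") <- params
  attr(out, "settings") <- settings
  attr(out, "gain") <- lambda
  out
}

# linear interpolation of a symmetric half-grid density at arbitrary errors
interp_density_half <- function(half, eps, step) {
  x <- abs(wrap_angle(eps)) / step
  i <- pmin(floor(x), length(half) - 2)
  t <- x - i
  half[i + 1L] * (1 - t) + half[i + 2L] * t
}

#' Evaluate a tabulated error density at arbitrary angles
#'
#' Linear interpolation on the circular grid of an [error_density()] table.
#'
#' @param density An `rc_density` tibble.
#' @param eps Angles (radians) at which to evaluate.
#' @return Interpolated densities.
#' @export
density_at <- function(density, eps) {
  stopifnot(inherits(density, "rc_density"))
  settings <- attr(density, "settings")
  step <- settings$step_deg * pi / 180
  np <- round(pi / step) + 1L
  half <- density$density[density$error >= -1e-12][seq_len(np - 1L)]
  half <- c(half, density$density[1])   # value at +pi == value at -pi
  interp_density_half(half, eps, step)
}

#' Export / import a tabulated error density
#'
#' Writes the grid as delimited text with a commented metadata header
#' (parameters, gain, method, seed and draw count) so densities can be cached
#' across fits and sessions; `read_density()` restores the tibble and
#' metadata.
#'
#' @param density An `rc_density` tibble.
#' @param path File path.
#' @return `write_density()` returns `path` invisibly; `read_density()`
#'   returns the `rc_density` tibble.
#' @export
write_density <- function(density, path) {
  stopifnot(inherits(density, "rc_density"))
  p <- attr(density, "params")
  s <- attr(density, "settings")
  hdr <- c(
    sprintf("# retropop error density"),
    sprintf("# rmax=%.15g fwhm=%.15g window=%.15g n_neurons=%d pswap=%.15g pguess=%.15g",
            p$rmax, p$fwhm, p$window, p$n_neurons, p$pswap, p$pguess),
    sprintf("# gain=%.15g method=%s step_deg=%.15g n_draws=%d seed=%d",
            attr(density, "gain"), s$method, s$step_deg, s$n_draws, s$seed))
  writeLines(hdr, path)
  readr::write_csv(tibble::as_tibble(density[c("error", "density")]), path,
                   append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_density
#' @export
read_density <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  tab <- readr::read_csv(I(lines[!startsWith(lines, "#")]),
                         show_col_types = FALSE, progress = FALSE)
  meta <- paste(sub("^# ?", "", hdr[-1]), collapse = " ")
  get_num <- function(kk) as.numeric(sub(paste0(".*", kk, "=([-0-9.eE+]+).*"), "\\1", meta))
  params <- pop_params(rmax = get_num("rmax"), fwhm = get_num("fwhm"),
                       window = get_num("window"),
                       n_neurons = get_num("n_neurons"),
                       pswap = get_num("pswap"), pguess = get_num("pguess"))
  step_deg <- get_num("step_deg")
  out <- tibble::as_tibble(tab)
  class(out) <- c("rc_density", class(out))
  attr(out, "params") <- params
  attr(out, "settings") <- density_settings(step_deg = step_deg)
  attr(out, "gain") <- get_num("gain")
  out
}

#' Log likelihood of a trial table under the population-coding model
#'
#' @description
#' Per-trial response density under the population-coding model with swap and
#' guess extensions:
#' \deqn{(1 - p_s - p_g)\, p_{pop}(r - t) + \frac{p_s}{m} \sum_j p_{pop}(r - d_j)
#'   + \frac{p_g}{2\pi}}
#' where `p_pop` is the predicted error density, `t` the target, `d_j` the
#' `m = set_size - 1` non-targets. All trials must share one set size (each
#' set size is treated as an independent data set); for set size 1 the swap
#' term is absent and `pswap` must be 0. Per-trial densities are floored at
#' `settings$floor` to guard underflow in extreme tails.
#'
#' @param trials Canonical trial table, single set size.
#' @param params A [pop_params()] object.
#' @param settings A [density_settings()] object.
#' @return The summed log likelihood (scalar).
#' @export
popmodel_loglik <- function(trials, params, settings = density_settings()) {
  stopifnot(inherits(params, "pop_params"))
  ss <- unique(trials$set_size)
  if (length(ss) != 1) abort("all trials must share one set size; fit set sizes separately.")
  m <- ss - 1L
  if (m == 0L && params$pswap > 0) {
    abort("pswap must be 0 when set size is 1 (no non-targets to swap to).")
  }
  half <- switch(settings$method,
    quadrature = pop_density_half(pop_gain(params), params$kappa, settings),
    mc = pop_density_half_mc(pop_gain(params), params$kappa, settings))
  step <- settings$step_deg * pi / 180
  dens <- trial_mixture_density(trials, params$pswap, params$pguess,
                                function(eps) interp_density_half(half, eps, step))
  sum(log(pmax(dens, settings$floor)))
}

# shared mixture assembly over target / non-target / uniform components
trial_mixture_density <- function(trials, pswap, pguess, dens_fun) {
  eps_t <- wrap_angle(trials$response - trials$target)
  p <- (1 - pswap - pguess) * dens_fun(eps_t) + pguess / (2 * pi)
  m <- unique(trials$set_size) - 1L
  if (m > 0L && pswap > 0) {
    nt <- nontarget_matrix(trials)[, seq_len(m), drop = FALSE]
    acc <- 0
    for (j in seq_len(m)) {
      acc <- acc + dens_fun(wrap_angle(trials$response - nt[, j]))
    }
    p <- p + pswap / m * acc
  }
  p
}
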