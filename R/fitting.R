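#' Specify a model variant to fit
#'
#' The five variants considered by the analysis pipeline are the
#' population-coding model (`"popcode"`: parameters `rmax`, `fwhm`),
#' optionally extended with swaps (`+ pswap`) and/or guessing (`+ pguess`),
#' and the von Mises + uniform mixture (`"normal_uniform"`: `kappa_prime`,
#' `pguess`), optionally extended with swaps. The free-parameter count `k`
#' follows from the flags: `k = 2 + with_swaps + with_guess` (popcode),
#' `k = 2 + with_swaps` (normal_uniform, whose base model already includes
#' the guess component).
#'
#' @param family `"popcode"` or `"normal_uniform"`.
#' @param with_swaps Include the swap-error component?
#' @param with_guess Include a random-guess component (popcode only; the
#'   mixture model always has one).
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("popcode", with_swaps = TRUE)
#' @export
model_spec <- function(family = c("popcode", "normal_uniform"),
                       with_swaps = FALSE, with_guess = FALSE) {
  family <- match.arg(family)
  if (family == "normal_uniform" && with_guess) {
    abort("the normal_uniform family always includes the guess component; `with_guess` applies to popcode only.")
  }
  k <- if (family == "popcode") 2L + with_swaps + with_guess else 2L + with_swaps
  structure(list(family = family, with_swaps = with_swaps,
                 with_guess = with_guess, k = as.integer(k)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s%s%s (k=%d)\n", x$family,
              if (x$with_swaps) "+swap" else "",
              if (x$with_guess) "+guess" else "", x$k))
  invisible(x)
}

model_label <- function(spec) {
  paste0(spec$family, if (x_or(spec$with_swaps)) "+swap" else "",
         if (x_or(spec$with_guess)) "+guess" else "")
}
x_or <- function(x) isTRUE(x)

#' Fitting options
#'
#' @param n_starts Number of Nelder-Mead restarts from dispersed (Latin
#'   hypercube) initial points (default 10).
#' @param maxit Maximum function evaluations per start (default 5000).
#' @param reltol Relative convergence tolerance of the simplex (default 1e-6).
#' @param min_trials Minimum trials required per fit (default 20).
#' @param window,n_neurons Fixed (non-fitted) population constants for
#'   popcode fits; see [pop_params()]. `window = NULL` (default) means
#'   `1/n_neurons`.
#' @param settings [density_settings()] used for popcode likelihoods.
#' @param init_ranges Plausible ranges for the dispersed starts, a named list
#'   with entries `rmax`, `fwhm`, `kappa_prime`, `prob`.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(n_starts = 10L, maxit = 5000L, reltol = 1e-6,
                        min_trials = 20L, window = NULL, n_neurons = 100L,
                        settings = density_settings(),
                        init_ranges = list(rmax = c(1, 100), fwhm = c(0.3, 3),
                                           kappa_prime = c(1, 50),
                                           prob = c(0.01, 0.3))) {
  structure(list(n_starts = as.integer(n_starts), maxit = as.integer(maxit),
                 reltol = reltol, min_trials = as.integer(min_trials),
                 window = window, n_neurons = as.integer(n_neurons),
                 settings = settings, init_ranges = init_ranges),
            class = "fit_options")
}

# ---- parameter transforms ---------------------------------------------------
# Fits run in an unconstrained space: log for rmax, shifted log for the
# tuning concentration (kappa > ln2/2 <=> fwhm < 2*pi), log for kappa'
# (capped), and an additive log-ratio transform for the probability simplex
# (pswap, pguess, remainder), which enforces pswap + pguess <= 1 by
# construction.

KAPPA_MIN_POP <- log(2) / 2
KAPPA_PRIME_CAP <- 1e4

free_prob_names <- function(spec) {
  c(if (x_or(spec$with_swaps)) "pswap",
    if (spec$family == "normal_uniform" || x_or(spec$with_guess)) "pguess")
}

transform_params <- function(values, spec) {
  pn <- free_prob_names(spec)
  probs <- unlist(values[pn])
  alr <- if (length(probs)) log(probs / (1 - sum(probs))) else numeric(0)
  if (spec$family == "popcode") {
    unname(c(log(values$rmax), log(values$kappa - KAPPA_MIN_POP), alr))
  } else {
    unname(c(log(values$kappa_prime), alr))
  }
}

untransform_params <- function(theta, spec) {
  pn <- free_prob_names(spec)
  np <- length(pn)
  alr <- if (np) theta[(length(theta) - np + 1):length(theta)] else numeric(0)
  e <- exp(alr)
  probs <- setNames(as.list(unname(e / (1 + sum(e)))), pn)
  out <- list(pswap = probs$pswap %||% 0, pguess = probs$pguess %||% 0)
  if (spec$family == "popcode") {
    out$rmax <- exp(theta[1])
    out$kappa <- KAPPA_MIN_POP + exp(theta[2])
    out$fwhm <- fwhm_from_kappa(out$kappa)
  } else {
    out$kappa_prime <- min(exp(theta[1]), KAPPA_PRIME_CAP)
  }
  out
}

params_object <- function(values, spec, options) {
  if (spec$family == "popcode") {
    pop_params(rmax = values$rmax, kappa = values$kappa,
               window = options$window, n_neurons = options$n_neurons,
               pswap = values$pswap, pguess = values$pguess)
  } else {
    mixture_params(kappa_prime = values$kappa_prime,
                   pguess = values$pguess, pswap = values$pswap)
  }
}

# dispersed Latin-hypercube starts over the plausible ranges (log scale for
# scale parameters), already transformed to the unconstrained space
dispersed_starts <- function(spec, options, n) {
  d <- spec$k
  u <- vapply(seq_len(d), function(j) (sample(n) - runif(n)) / n,
              numeric(n))
  u <- matrix(u, nrow = n)
  rng <- options$init_ranges
  pn <- free_prob_names(spec)
  lapply(seq_len(n), function(i) {
    vals <- list()
    col <- 1
    if (spec$family == "popcode") {
      vals$rmax <- exp(log(rng$rmax[1]) + u[i, 1] * diff(log(rng$rmax)))
      fw <- rng$fwhm[1] + u[i, 2] * diff(rng$fwhm)
      vals$kappa <- kappa_from_fwhm(fw)
      col <- 3
    } else {
      vals$kappa_prime <- exp(log(rng$kappa_prime[1]) +
                                u[i, 1] * diff(log(rng$kappa_prime)))
      col <- 2
    }
    for (p in pn) {
      vals[[p]] <- rng$prob[1] + u[i, col] * diff(rng$prob)
      col <- col + 1
    }
    transform_params(vals, spec)
  })
}

#' Akaike Information Criterion
#'
#' `AIC = 2k - 2*loglik`; lower is better.
#'
#' @param loglik Maximized log likelihood.
#' @param k Number of free parameters (`>= 1`).
#' @return The AIC value.
#' @export
aic <- function(loglik, k) {
  stopifnot(k >= 1)
  2 * k - 2 * loglik
}

#' Maximum-likelihood fit of a model variant to one data set
#'
#' @description
#' Fits a [model_spec()] to the trials of a single subject x condition x
#' set-size group by Nelder-Mead maximization of the log likelihood in an
#' unconstrained transformed space (log for `rmax` and concentrations,
#' additive log-ratio for the probability simplex, so fitted probabilities
#' always satisfy `pswap + pguess <= 1`). The best of `n_starts` dispersed
#' restarts is returned. The quadrature likelihood surface is deterministic,
#' so identical data, options and seed reproduce the fit exactly.
#'
#' @param trials Canonical trial table (one set size; intended for one
#'   subject and condition).
#' @param spec A [model_spec()].
#' @param options A [fit_options()] list.
#' @param seed Integer seed controlling the dispersed starts (and the Monte
#'   Carlo density noise when `options$settings$method == "mc"`).
#' @return An object of class `rc_fit`: a list with `params` (a
#'   [pop_params()] or [mixture_params()] object), `estimates` (named numeric
#'   of free parameters), `loglik`, `aic`, `k`, `n_trials`, `starts` (tibble
#'   of per-start outcomes), `converged`, `spec`, `seed`.
#' @seealso [fit_participants()] to map over a whole trial table,
#'   [compare_models()] for AIC comparison.
#' @export
fit_mle <- function(trials, spec, options = fit_options(), seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), inherits(options, "fit_options"))
  validate_trials(trials)
  if (nrow(trials) < options$min_trials) {
    abort(sprintf("%d trials is fewer than the configured minimum of %d.",
                  nrow(trials), options$min_trials), class = "retropop_few_trials")
  }
  ss <- unique(trials$set_size)
  if (length(ss) != 1) abort("all trials must share one set size; fit set sizes separately.")
  if (ss == 1L && x_or(spec$with_swaps)) {
    abort("cannot fit a swap component at set size 1.", class = "retropop_model_spec")
  }
  settings <- options$settings
  if (settings$method == "mc") {
    # common random numbers: one noise seed per fit so the Monte Carlo
    # likelihood surface is deterministic within the fit
    settings$seed <- as.integer((seed * 7919 + 13) %% .Machine$integer.max)
  }
  objective <- function(theta) {
    values <- untransform_params(theta, spec)
    ll <- tryCatch({
      if (spec$family == "popcode") {
        popmodel_loglik(trials, params_object(values, spec, options), settings)
      } else {
        mixture_loglik(trials, params_object(values, spec, options),
                       floor = settings$floor)
      }
    }, retropop_gain_cap = function(e) -Inf)
    if (!is.finite(ll)) 1e12 else -ll
  }
  starts <- withr::with_seed(seed, dispersed_starts(spec, options, options$n_starts))
  runs <- lapply(seq_along(starts), function(i) {
    th0 <- starts[[i]]
    f0 <- objective(th0)
    opt <- optim(th0, objective, method = "Nelder-Mead",
                 control = list(maxit = options$maxit, reltol = options$reltol))
    tibble::tibble(start = i, loglik0 = -f0, loglik = -opt$value,
                   evals = opt$counts[["function"]],
                   converged = opt$convergence == 0,
                   theta = list(opt$par))
  })
  runs <- dplyr::bind_rows(runs)
  best <- which.max(runs$loglik)
  values <- untransform_params(runs$theta[[best]], spec)
  params <- params_object(values, spec, options)
  est <- unlist(values[c(intersect(c("rmax", "fwhm", "kappa_prime"), names(values)),
                         free_prob_names(spec))])
  ll <- runs$loglik[best]
  structure(list(
    params = params,
    estimates = est,
    loglik = ll,
    aic = aic(ll, spec$k),
    k = spec$k,
    n_trials = nrow(trials),
    starts = runs[c("start", "loglik0", "loglik", "evals", "converged")],
    converged = any(runs$loglik > runs$loglik0 + 1e-9) || any(runs$converged),
    spec = spec,
    options = options,
    seed = seed
  ), class = "rc_fit")
}

#' @export
print.rc_fit <- function(x, ...) {
  cat(sprintf("<rc_fit> %s  loglik=%.2f AIC=%.2f n=%d%s\n",
              model_label(x$spec), x$loglik, x$aic, x$n_trials,
              if (!x$converged) " [not converged]" else ""))
  print(round(x$estimates, 4))
  invisible(x)
}

#' @describeIn fit_mle Tidy the fitted parameters into a one-row-per-term
#'   tibble.
#' @param x An `rc_fit` object.
#' @param ... Unused.
#' @export
tidy.rc_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates), estimate = unname(x$estimates))
}

#' @describeIn fit_mle One-row model summary (loglik, AIC, trials,
#'   convergence).
#' @export
glance.rc_fit <- function(x, ...) {
  tibble::tibble(model = model_label(x$spec), loglik = x$loglik, aic = x$aic,
                 k = x$k, n_trials = x$n_trials, n_starts = nrow(x$starts),
                 converged = x$converged, seed = x$seed)
}

#' Fit a model to every participant group of a trial table
#'
#' Maps [fit_mle()] over subject x condition x set-size (x experiment) groups
#' and returns one row per group with the fitted parameters unpacked into
#' columns. Groups with fewer than `options$min_trials` trials are dropped
#' with a message.
#'
#' @inheritParams fit_mle
#' @param trials Canonical trial table (any number of groups).
#' @return A tibble with grouping columns, parameter estimates, `loglik`,
#'   `aic`, `converged`, `n_trials`, `model`, and the full `rc_fit` in the
#'   list-column `fit`.
#' @export
fit_participants <- function(trials, spec, options = fit_options(), seed = 1L) {
  validate_trials(trials)
  keys <- intersect(c("experiment", "subject", "condition", "set_size"),
                    names(trials))
  grouped <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    tidyr::nest() |>
    dplyr::ungroup()
  sizes <- vapply(grouped$data, nrow, integer(1))
  drop <- sizes < options$min_trials
  if (any(drop)) {
    inform(sprintf("dropping %d group(s) with fewer than %d trials",
                   sum(drop), options$min_trials))
    grouped <- grouped[!drop, , drop = FALSE]
  }
  fits <- purrr::imap(grouped$data, function(d, i) {
    g <- grouped[i, keys, drop = FALSE]
    d[names(g)] <- g
    fit_mle(d, spec, options, seed = seed + i - 1L)
  })
  est <- dplyr::bind_rows(lapply(fits, function(f) as.list(f$estimates)))
  dplyr::bind_cols(
    grouped[keys],
    est,
    tibble::tibble(
      loglik = vapply(fits, `[[`, numeric(1), "loglik"),
      aic = vapply(fits, `[[`, numeric(1), "aic"),
      converged = vapply(fits, `[[`, logical(1), "converged"),
      n_trials = vapply(fits, `[[`, numeric(1), "n_trials"),
      model = model_label(spec),
      fit = fits
    )
  )
}

#' Compare two fitted models across participants by AIC
#'
#' Computes per-participant `delta_aic = aic_a - aic_b` (positive values
#' favour model B), the group total, the fraction of participants favouring
#' model B, and a two-sided exact sign test on the signs of the differences
#' (ties dropped; with no non-tied participants the fraction is reported as
#' 0.5 and p as 1).
#'
#' @param fits_a,fits_b Fit tables from [fit_participants()] for the same
#'   participants (matched on their grouping columns).
#' @return An object of class `rc_comparison` with elements `per_participant`
#'   (tibble), `total_delta_aic`, `fraction_favoring_b`, `sign_test_p`,
#'   `model_a`, `model_b`, `n`.
#' @export
compare_models <- function(fits_a, fits_b) {
  keys <- intersect(intersect(c("experiment", "subject", "condition", "set_size"),
                              names(fits_a)), names(fits_b))
  if (length(keys) == 0) abort("fit tables share no grouping columns.")
  a <- fits_a[c(keys, "aic")]
  b <- fits_b[c(keys, "aic")]
  names(a)[names(a) == "aic"] <- "aic_a"
  names(b)[names(b) == "aic"] <- "aic_b"
  j <- dplyr::inner_join(a, b, by = keys)
  if (nrow(j) != nrow(a) || nrow(j) != nrow(b)) {
    abort("participant groups do not match between the two fit tables.")
  }
  j$delta_aic <- j$aic_a - j$aic_b
  signs <- sign(j$delta_aic)
  nz <- signs[signs != 0]
  st <- if (length(nz) == 0) {
    list(p.value = 1)
  } else {
    binom.test(sum(nz > 0), length(nz), p = 0.5)
  }
  structure(list(
    per_participant = j,
    total_delta_aic = sum(j$delta_aic),
    fraction_favoring_b = if (length(nz) == 0) 0.5 else mean(nz > 0),
    sign_test_p = st$p.value,
    model_a = fits_a$model[1] %||% "A",
    model_b = fits_b$model[1] %||% "B",
    n = nrow(j)
  ), class = "rc_comparison")
}

#' @export
print.rc_comparison <- function(x, ...) {
  cat(sprintf("<rc_comparison> %s vs %s (n=%d)\n", x$model_a, x$model_b, x$n))
  cat(sprintf("  total dAIC (A-B) = %.1f; %.0f%% favour B; sign test p = %.4g\n",
              x$total_delta_aic, 100 * x$fraction_favoring_b, x$sign_test_p))
  invisible(x)
}

#' @describeIn compare_models Per-participant AIC differences as a tibble.
#' @param x An `rc_comparison` object.
#' @param ... Unused.
#' @export
tidy.rc_comparison <- function(x, ...) x$per_participant

#' @describeIn compare_models One-row summary of the comparison.
#' @export
glance.rc_comparison <- function(x, ...) {
  tibble::tibble(model_a = x$model_a, model_b = x$model_b, n = x$n,
                 total_delta_aic = x$total_delta_aic,
                 fraction_favoring_b = x$fraction_favoring_b,
                 sign_test_p = x$sign_test_p)
}
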