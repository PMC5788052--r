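#' Population-coding model parameters
#'
#' @description
#' Parameters of the stochastic population-coding model of recall. A remembered
#' feature value is encoded in the spiking of a population of idealized neurons
#' with von Mises tuning curves; recall is maximum a posteriori decoding of the
#' spikes emitted in a fixed readout window. The tuning curve of neuron `i`
#' with preferred value `phi_i` is
#'
#' \deqn{\lambda_i(\theta) = r_{max}\, w \, \exp\{\kappa(\cos(\theta-\phi_i)-1)\}}
#'
#' with peak expected count `rmax * window` and concentration `kappa`,
#' parameterized by the full-width at half-maximum
#' `fwhm = 2 * acos(1 - ln 2 / kappa)`. Spike counts are independent Poisson.
#' The expected total count over the population (the population gain) is
#' `lambda = n_neurons * rmax * window * exp(-kappa) * I0(kappa)`; only this
#' product is identified by behaviour, so `window` fixes the unit convention.
#' The default `window = 1/n_neurons` makes the gain independent of the
#' (arbitrary) population size, `lambda = rmax * exp(-kappa) * I0(kappa)`,
#' so that peak rates in the empirically observed range (`rmax ~ 15`, `fwhm
#' ~ 1.25`) read out a handful of spikes per recall — the regime that
#' produces the sharply peaked, long-tailed error distributions
#' characteristic of working memory (see the package vignette).
#'
#' `pswap` is the probability that decoding is inadvertently centred on a
#' non-target item (a swap error); `pguess` the probability of a uniformly
#' random response. The unextended model has both at 0.
#'
#' @param rmax Peak expected spike count per unit window (`>= 0`).
#' @param fwhm Tuning full-width at half-maximum in internal radians,
#'   in `(0, 2*pi)`. Give either `fwhm` or `kappa`.
#' @param kappa Tuning concentration (alternative to `fwhm`).
#' @param window Readout-window scale factor (dimensionless; multiplies every
#'   expected count). Default `1/n_neurons`.
#' @param n_neurons Number of neurons `M`, preferred values evenly spaced on
#'   the circle (default 100).
#' @param pswap,pguess Swap and guess probabilities, `pswap + pguess <= 1`.
#' @return An object of class `pop_params`.
#' @examples
#' p <- pop_params(rmax = 15, fwhm = 1.25)
#' pop_gain(p)   # expected total spike count per decode
#' @export
pop_params <- function(rmax, fwhm = NULL, kappa = NULL, window = NULL,
                       n_neurons = 100L, pswap = 0, pguess = 0) {
  if (is.null(kappa) == is.null(fwhm)) {
    abort("give exactly one of `fwhm` or `kappa`.")
  }
  if (is.null(window)) window <- 1 / n_neurons
  if (is.null(kappa)) kappa <- kappa_from_fwhm(fwhm)
  if (is.null(fwhm)) fwhm <- fwhm_from_kappa(kappa)
  stopifnot(rmax >= 0, window > 0, n_neurons >= 1,
            pswap >= 0, pguess >= 0)
  if (pswap + pguess > 1 + 1e-12) abort("pswap + pguess must not exceed 1.")
  structure(list(rmax = rmax, fwhm = fwhm, kappa = kappa, window = window,
                 n_neurons = as.integer(n_neurons),
                 pswap = pswap, pguess = pguess),
            class = "pop_params")
}

#' @export
print.pop_params <- function(x, ...) {
  cat(sprintf(
    "<pop_params> rmax=%.4g fwhm=%.4g (kappa=%.4g) window=%.3g M=%d pswap=%.3g pguess=%.3g gain=%.4g\n",
    x$rmax, x$fwhm, x$kappa, x$window, x$n_neurons, x$pswap, x$pguess,
    pop_gain(x)))
  invisible(x)
}

#' Convert tuning width between FWHM and von Mises concentration
#'
#' The von Mises tuning profile `exp(kappa * (cos(d) - 1))` falls to half its
#' peak where `kappa * (cos(d) - 1) = -ln 2`, giving
#' `kappa = ln 2 / (1 - cos(fwhm / 2))` and inverse
#' `fwhm = 2 * acos(1 - ln 2 / kappa)`. Concentrations below `ln(2)/2` have a
#' half-maximum wider than the circle; `fwhm_from_kappa()` then returns the
#' sentinel `2*pi`.
#'
#' @param fwhm Full-width at half-maximum in radians, in `(0, 2*pi)`.
#' @param kappa Concentration, `kappa > 0`.
#' @return The corresponding concentration / width.
#' @examples
#' fwhm_from_kappa(log(2))                 # pi
#' kappa_from_fwhm(fwhm_from_kappa(3.83))  # round trip
#' @export
kappa_from_fwhm <- function(fwhm) {
  if (any(!is.finite(fwhm)) || any(fwhm <= 0) || any(fwhm >= 2 * pi)) {
    abort("`fwhm` must lie strictly inside (0, 2*pi).")
  }
  log(2) / (1 - cos(fwhm / 2))
}

#' @rdname kappa_from_fwhm
#' @export
fwhm_from_kappa <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa <= 0)) {
    abort("`kappa` must be positive.")
  }
  ifelse(kappa < log(2) / 2, 2 * pi, 2 * acos(1 - log(2) / kappa))
}

#' Expected spike counts of the tuned population
#'
#' Expected Poisson means `lambda_i = rmax * window *
#' exp(kappa * (cos(theta - phi_i) - 1))` for a population of `n_neurons`
#' neurons with evenly spaced preferred values.
#'
#' @param theta Encoded stimulus value (radians, scalar).
#' @param params A [pop_params()] object.
#' @return Numeric vector of length `n_neurons` of expected counts; preferred
#'   values are attached as attribute `"preferred"`.
#' @export
expected_rates <- function(theta, params) {
  stopifnot(inherits(params, "pop_params"), length(theta) == 1L, is.finite(theta))
  phi <- preferred_values(params$n_neurons)
  lam <- params$rmax * params$window *
    exp(params$kappa * (cos(theta - phi) - 1))
  attr(lam, "preferred") <- phi
  lam
}

preferred_values <- function(M) seq(-pi, pi, length.out = M + 1L)[seq_len(M)]

#' Expected total spike count (population gain)
#'
#' `lambda = n_neurons * rmax * window * exp(-kappa) * I0(kappa)`, the
#' dense-population limit of the summed tuning curves, which the predicted
#' error distribution depends on (together with `kappa`).
#'
#' @param params A [pop_params()] object.
#' @return Expected total spike count per decode.
#' @export
pop_gain <- function(params) {
  stopifnot(inherits(params, "pop_params"))
  params$n_neurons * params$rmax * params$window *
    exp(log_bessel_I0(params$kappa) - params$kappa)
}

#' Simulate a spike pattern
#'
#' Draws independent Poisson spike counts from the population tuned to
#' `theta`. Reproducible under a fixed seed.
#'
#' @param theta Encoded stimulus value (radians).
#' @param params A [pop_params()] object.
#' @param seed Optional integer; when given, sampling runs under this seed
#'   without disturbing the global RNG state.
#' @return A list of class `spike_pattern` with `counts`, `preferred`, and
#'   `stimulus`.
#' @export
sample_spikes <- function(theta, params, seed = NULL) {
  lam <- expected_rates(theta, params)
  draw <- function() rpois(length(lam), lam)
  counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(list(counts = counts, preferred = attr(lam, "preferred"),
                 stimulus = theta),
            class = "spike_pattern")
}

#' Maximum a posteriori decoding of a spike pattern
#'
#' @description
#' The decoder maximizes the Poisson log likelihood
#' \deqn{\sum_i n_i \log \lambda_i(\theta) - \sum_i \lambda_i(\theta)}
#' over candidate stimulus values. For evenly spaced preferred values the
#' penalty term is independent of `theta` (up to a vanishing discretization
#' ripple), so the maximizer is the direction of the spike-weighted resultant
#' \eqn{\sum_i n_i e^{j\phi_i}}. A pattern with no spikes, or an exactly
#' antipodal resultant, carries no direction information: the estimate is then
#' drawn uniformly and flagged degenerate — these trials are the model's
#' intrinsic "guesses".
#'
#' @param spikes A `spike_pattern` from [sample_spikes()] (or a compatible
#'   list with `counts` and `preferred`).
#' @param params A [pop_params()] object consistent with `spikes`.
#' @param seed Optional integer seed for the degenerate tie-break draw.
#' @return A list with `estimate` (radians) and `degenerate` (logical).
#' @export
decode_map <- function(spikes, params, seed = NULL) {
  stopifnot(length(spikes$counts) == length(spikes$preferred))
  if (!is.null(params)) {
    stopifnot(inherits(params, "pop_params"),
              length(spikes$counts) == params$n_neurons)
  }
  degenerate <- sum(spikes$counts) == 0
  if (!degenerate) {
    cm <- circ_mean(spikes$preferred, weights = spikes$counts + 0)
    degenerate <- cm$degenerate
  }
  if (degenerate) {
    draw <- function() runif(1, -pi, pi)
    est <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    return(list(estimate = est, degenerate = TRUE))
  }
  list(estimate = cm$direction, degenerate = FALSE)
}
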