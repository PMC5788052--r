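#' Von Mises + uniform mixture model parameters
#'
#' Parameters of the classical descriptive model of continuous-report recall:
#' with probability `1 - pguess - pswap` the response is von Mises distributed
#' (concentration `kappa_prime`) around the target; with probability `pguess`
#' it is uniformly random; with probability `pswap` it is von Mises
#' distributed around one of the non-target items (a swap error). A single
#' `kappa_prime` is shared by the target and non-target components.
#'
#' @param kappa_prime Von Mises concentration, `>= 0` (capped at `1e4` during
#'   fitting to keep Bessel evaluation stable; fitted values in practice are
#'   orders of magnitude below the cap).
#' @param pguess,pswap Mixture probabilities, `pguess + pswap <= 1`.
#' @return An object of class `mixture_params`.
#' @export
mixture_params <- function(kappa_prime, pguess = 0, pswap = 0) {
  stopifnot(kappa_prime >= 0, pguess >= 0, pswap >= 0)
  if (pguess + pswap > 1 + 1e-12) abort("pguess + pswap must not exceed 1.")
  structure(list(kappa_prime = kappa_prime, pguess = pguess, pswap = pswap),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("<mixture_params> kappa'=%.4g pguess=%.3g pswap=%.3g\n",
              x$kappa_prime, x$pguess, x$pswap))
  invisible(x)
}

#' Response density under the von Mises + uniform mixture
#'
#' \deqn{(1 - p_g - p_s)\,VM(r - t; \kappa') + \frac{p_g}{2\pi}
#'   + \frac{p_s}{m}\sum_j VM(r - d_j; \kappa')}
#'
#' @param response,target Angles in internal radians.
#' @param nontargets Numeric vector of non-target angles (may be empty when
#'   `pswap = 0`).
#' @param params A [mixture_params()] object.
#' @return Density value(s).
#' @export
mixture_pdf <- function(response, target, nontargets = numeric(0), params) {
  stopifnot(inherits(params, "mixture_params"))
  m <- length(nontargets)
  if (params$pswap > 0 && m == 0) {
    abort("pswap > 0 requires at least one non-target.", class = "retropop_model_spec")
  }
  p <- (1 - params$pguess - params$pswap) *
    vm_pdf(wrap_angle(response - target), params$kappa_prime) +
    params$pguess / (2 * pi)
  if (m > 0 && params$pswap > 0) {
    acc <- 0
    for (d in nontargets) {
      acc <- acc + vm_pdf(wrap_angle(response - d), params$kappa_prime)
    }
    p <- p + params$pswap / m * acc
  }
  p
}

#' Log likelihood of a trial table under the mixture model
#'
#' Sum of `log` [mixture_pdf()] over trials; all trials must share one set
#' size. Densities are floored at `floor` to guard underflow.
#'
#' @param trials Canonical trial table, single set size.
#' @param params A [mixture_params()] object.
#' @param floor Per-trial density floor (default `1e-10`).
#' @return The summed log likelihood (scalar).
#' @export
mixture_loglik <- function(trials, params, floor = 1e-10) {
  stopifnot(inherits(params, "mixture_params"))
  ss <- unique(trials$set_size)
  if (length(ss) != 1) abort("all trials must share one set size; fit set sizes separately.")
  if (ss == 1L && params$pswap > 0) {
    abort("pswap must be 0 when set size is 1.", class = "retropop_model_spec")
  }
  dens <- trial_mixture_density(trials, params$pswap, params$pguess,
                                function(eps) vm_pdf(eps, params$kappa_prime))
  sum(log(pmax(dens, floor)))
}
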