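#' Plot a predicted error density
#'
#' @param object An `rc_density` from [error_density()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rc_density <- function(object, ...) {
  p <- attr(object, "params")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$error, y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#b2182b") +
    ggplot2::labs(
      x = "error (rad)", y = "probability density",
      title = "Predicted recall-error density (population coding)",
      subtitle = sprintf("rmax = %.3g, FWHM = %.3g, gain = %.3g",
                         p$rmax, p$fwhm, attr(object, "gain"))) +
    ggplot2::theme_minimal()
}

#' Plot a chance-corrected non-target histogram
#'
#' @param object An `rc_hist` from [chance_corrected_hist()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rc_hist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center,
                                       y = .data$corrected_density)) +
    ggplot2::geom_col(width = diff(object$bin_center[1:2]) * 0.9,
                      fill = "grey35") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "deviation from non-target (rad)",
                  y = "density - chance",
                  title = "Chance-corrected deviations around non-targets") +
    ggplot2::theme_minimal()
}

#' Plot a fitted model against the observed error histogram
#'
#' @param object An `rc_fit` from [fit_mle()].
#' @param trials The trial table the model was fitted to.
#' @param bins Number of histogram bins (default 60).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rc_fit <- function(object, trials, bins = 60, ...) {
  eps <- circ_dist(trials$response, trials$target)
  grid <- seq(-pi, pi, length.out = 361)
  pred <- predict_error_density(object, trials, grid)
  df_h <- tibble::tibble(eps = eps)
  df_c <- tibble::tibble(error = grid, density = pred)
  ggplot2::ggplot(df_h, ggplot2::aes(x = .data$eps)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey60") +
    ggplot2::geom_line(data = df_c,
                       ggplot2::aes(x = .data$error, y = .data$density),
                       colour = "#b2182b", linewidth = 0.9) +
    ggplot2::labs(x = "response - target (rad)", y = "density",
                  title = sprintf("Observed errors and fitted %s model",
                                  model_label(object$spec))) +
    ggplot2::theme_minimal()
}

# model-predicted density of response-minus-target for plotting: mixes the
# target component with the swap components implied by the actual non-target
# geometry of the trials, plus the uniform guess floor
predict_error_density <- function(fit, trials, grid) {
  params <- fit$params
  if (inherits(params, "pop_params")) {
    settings <- fit$options$settings
    half <- pop_density_half(pop_gain(params), params$kappa, settings)
    step <- settings$step_deg * pi / 180
    dens_fun <- function(e) interp_density_half(half, e, step)
    ps <- params$pswap; pg <- params$pguess
  } else {
    dens_fun <- function(e) vm_pdf(e, params$kappa_prime)
    ps <- params$pswap; pg <- params$pguess
  }
  base <- (1 - ps - pg) * dens_fun(grid) + pg / (2 * pi)
  if (ps > 0) {
    nt <- nontarget_matrix(trials)
    dev <- wrap_angle(nt[!is.na(nt)] -
                        trials$target[row(nt)[!is.na(nt)]])
    add <- rowMeans(vapply(dev, function(d) dens_fun(wrap_angle(grid - d)),
                           numeric(length(grid))))
    base <- base + ps * add
  }
  base
}

#' Plot a parameter-recovery summary
#'
#' Fitted parameter estimates per subject against the generating truth.
#'
#' @param object An `rc_recovery` from [recovery_study()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rc_recovery <- function(object, ...) {
  terms <- unique(object$summary$term)
  long <- object$fits |>
    dplyr::select(dplyr::all_of(c("subject", "condition", terms))) |>
    tidyr::pivot_longer(dplyr::all_of(terms), names_to = "term",
                        values_to = "estimate")
  truth <- dplyr::select(object$summary, dplyr::all_of(c("condition", "term", "truth")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$estimate)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 1) +
    ggplot2::geom_point(data = truth,
                        ggplot2::aes(y = .data$truth), colour = "#b2182b",
                        shape = 4, size = 3, stroke = 1.2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(y = "estimate (x = truth)", x = NULL,
                  title = "Parameter recovery") +
    ggplot2::theme_minimal()
}
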