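#' Design a synthetic retro-cue experiment
#'
#' @description
#' Describes a simulated delayed-estimation experiment with a retro-cue and a
#' control condition, generated forward from either the population-coding
#' model or the von Mises + uniform mixture. The defaults mirror a typical
#' collated-corpus study at desk scale: 20 subjects, 300 trials per
#' condition, set size 4, a 360-degree colour wheel, and population-coding
#' truth with a gain advantage and reduced swap rate for the retro-cued item.
#'
#' @param n_subjects Number of simulated subjects.
#' @param trials_per_condition Trials per subject in each condition.
#' @param set_size Number of array items (constant across trials).
#' @param feature_space A [feature_space()] (default 360-degree colour wheel).
#' @param min_separation Minimum pairwise circular separation between array
#'   feature values, internal radians (default 0; several source experiments
#'   enforce such separations, which is what the chance correction exists
#'   for). Must satisfy `min_separation * set_size < 2*pi`.
#' @param conditions Named list with elements `retrocue` and `control`, each
#'   a [pop_params()] or [mixture_params()] object (all of one class).
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `experiment_design`.
#' @examples
#' d <- experiment_design(n_subjects = 4, trials_per_condition = 50)
#' @export
experiment_design <- function(n_subjects = 20L, trials_per_condition = 300L,
                              set_size = 4L,
                              feature_space = retropop::feature_space("color", 360),
                              min_separation = 0,
                              conditions = list(
                                retrocue = pop_params(rmax = 19, fwhm = 1.25, pswap = 0.07),
                                control = pop_params(rmax = 15, fwhm = 1.25, pswap = 0.15)),
                              seed = 1L) {
  stopifnot(n_subjects >= 1, trials_per_condition >= 1, set_size >= 1,
            inherits(feature_space, "feature_space"), min_separation >= 0)
  if (trials_per_condition * n_subjects < 1) abort("empty design.")
  if (min_separation * set_size >= 2 * pi) {
    abort("min_separation * set_size must be < 2*pi for placements to be feasible.")
  }
  if (!setequal(names(conditions), c("retrocue", "control"))) {
    abort("`conditions` must have elements 'retrocue' and 'control'.")
  }
  classes <- vapply(conditions, function(p) class(p)[1], character(1))
  if (length(unique(classes)) != 1 ||
      !classes[1] %in% c("pop_params", "mixture_params")) {
    abort("both conditions must be pop_params or both mixture_params.")
  }
  family <- if (classes[1] == "pop_params") "popcode" else "normal_uniform"
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_condition = as.integer(trials_per_condition),
                 set_size = as.integer(set_size),
                 feature_space = feature_space,
                 min_separation = min_separation,
                 conditions = conditions, family = family,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %s generator: %d subjects x %d trials/condition, set size %d, seed %d\n",
              x$family, x$n_subjects, x$trials_per_condition, x$set_size, x$seed))
  invisible(x)
}

# rejection-sample `n_trials` arrays of `set_size` values with pairwise
# circular separation >= min_sep
sample_arrays <- function(n_trials, set_size, min_sep, max_attempts = 10000L) {
  if (min_sep <= 0 || set_size == 1L) {
    return(matrix(runif(n_trials * set_size, -pi, pi), nrow = n_trials))
  }
  out <- matrix(NA_real_, n_trials, set_size)
  need <- seq_len(n_trials)
  for (att in seq_len(max_attempts)) {
    cand <- matrix(runif(length(need) * set_size, -pi, pi), ncol = set_size)
    ok <- apply(cand, 1, function(v) {
      d <- abs(wrap_angle(outer(v, v, "-")))
      all(d[upper.tri(d)] >= min_sep)
    })
    out[need[ok], ] <- cand[ok, , drop = FALSE]
    need <- need[!ok]
    if (length(need) == 0) return(out)
  }
  abort(sprintf("could not place %d arrays with min_separation %.3f after %d attempts",
                length(need), min_sep, max_attempts),
        class = "retropop_placement")
}

# decoded responses of the population-coding model for a vector of encoded
# stimuli (finite-population simulator: Poisson spikes, resultant decoding,
# uniform tie-break on degenerate patterns)
decode_popcode_responses <- function(stimuli, params) {
  M <- params$n_neurons
  phi <- preferred_values(M)
  lam0 <- params$rmax * params$window
  # counts for trial t, neuron i: Poisson(lam0 * exp(kappa(cos(theta_t - phi_i) - 1)))
  L <- lam0 * exp(params$kappa * (cos(outer(stimuli, phi, "-")) - 1))
  counts <- matrix(rpois(length(L), L), nrow = length(stimuli))
  C <- as.vector(counts %*% cos(phi))
  S <- as.vector(counts %*% sin(phi))
  est <- atan2(S, C)
  degen <- sqrt(C^2 + S^2) < 1e-12
  est[degen] <- runif(sum(degen), -pi, pi)
  wrap_angle(est)
}

#' Generate a synthetic trial table
#'
#' @description
#' Runs the generative models forward under a fixed seed. Per trial: array
#' feature values are drawn uniformly subject to the pairwise minimum
#' separation (rejection sampling); item 1 is the probed target. The response
#' is, with probability `pguess`, uniform; with probability `pswap`, the
#' model's decode of a uniformly chosen non-target (swaps are full-fidelity
#' decodes of the wrong item); otherwise the model's decode of the target.
#' Population-coding decoding simulates Poisson spike counts in the finite
#' tuned population and decodes the spike-weighted resultant; zero-spike
#' patterns yield uniform responses (the model's intrinsic guesses). The
#' mixture generator adds von Mises error with concentration `kappa_prime`.
#'
#' @param design An [experiment_design()].
#' @return A canonical trial table (tibble, internal radians) with
#'   experiment label `"synthetic"`, subjects `s01, s02, ...`, and the design
#'   attached as attribute `"design"`; interchangeable with tables from
#'   [read_trials()].
#' @export
generate_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  withr::with_seed(design$seed, {
    purrr::map_dfr(c("retrocue", "control"), function(cond) {
      par <- design$conditions[[cond]]
      purrr::map_dfr(seq_len(design$n_subjects), function(s) {
        nt <- design$trials_per_condition
        arr <- sample_arrays(nt, design$set_size, design$min_separation)
        target <- arr[, 1]
        u <- runif(nt)
        pg <- par$pguess
        ps <- par$pswap
        stim <- target
        if (design$set_size > 1 && ps > 0) {
          is_swap <- u >= pg & u < pg + ps
          if (any(is_swap)) {
            pick <- sample.int(design$set_size - 1L, sum(is_swap), replace = TRUE) + 1L
            stim[is_swap] <- arr[cbind(which(is_swap), pick)]
          }
        }
        resp <- if (design$family == "popcode") {
          decode_popcode_responses(stim, par)
        } else {
          wrap_angle(stim + rvonmises(nt, par$kappa_prime))
        }
        is_guess <- u < pg
        resp[is_guess] <- runif(sum(is_guess), -pi, pi)
        row <- tibble::tibble(
          subject = sprintf("s%02d", s),
          experiment = "synthetic",
          condition = cond,
          control_kind = if (cond == "control") "neutral" else "none",
          set_size = design$set_size,
          target = target
        )
        if (design$set_size > 1) {
          nt_mat <- arr[, -1, drop = FALSE]
          colnames(nt_mat) <- paste0("nontarget_", seq_len(ncol(nt_mat)))
          row <- dplyr::bind_cols(row, tibble::as_tibble(nt_mat))
        }
        row$response <- resp
        row
      })
    }) -> out
    attr(out, "design") <- design
    attr(out, "spaces") <- setNames(list(design$feature_space), "synthetic")
    validate_trials(out)
    out
  })
}

#' Parameter-recovery study
#'
#' @description
#' Generates a synthetic experiment, fits `spec` to every subject x
#' condition group, and summarizes recovery: per parameter and condition the
#' truth, the median estimate across subjects, the bias (mean estimation
#' error, so RMSE >= |bias| always) and the RMSE; plus the group-level
#' condition contrasts the pipeline reports
#' (Wilcoxon signed-rank on the fitted gain and width parameters between
#' conditions).
#'
#' @param design An [experiment_design()]; its generator family should match
#'   `spec$family`.
#' @param spec A [model_spec()] to fit.
#' @param options [fit_options()] for the fits.
#' @param seed Integer seed for the fitting restarts (generation uses
#'   `design$seed`).
#' @return An object of class `rc_recovery`: list with `fits` (per-subject
#'   fit table), `summary` (tibble: condition, term, truth, median_estimate,
#'   bias, rmse), `contrasts` (tibble of Wilcoxon results per term), and
#'   `design`.
#' @export
recovery_study <- function(design, spec, options = fit_options(), seed = 1L) {
  stopifnot(inherits(design, "experiment_design"), inherits(spec, "model_spec"))
  if (design$family != spec$family) {
    abort("generator family and fitted model family differ; recovery is only meaningful within a family.")
  }
  trials <- generate_experiment(design)
  fits <- fit_participants(trials, spec, options, seed = seed)
  terms <- setdiff(intersect(c("rmax", "fwhm", "kappa_prime", "pswap", "pguess"),
                             names(fits)), character(0))
  truth_of <- function(cond, term) {
    v <- design$conditions[[cond]][[term]]
    if (is.null(v)) NA_real_ else v
  }
  summary <- tidyr::expand_grid(condition = c("retrocue", "control"),
                                term = terms) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      truth = truth_of(.data$condition, .data$term),
      median_estimate = median(fits[[.data$term]][fits$condition == .data$condition]),
      bias = mean(fits[[.data$term]][fits$condition == .data$condition]) - .data$truth,
      rmse = sqrt(mean((fits[[.data$term]][fits$condition == .data$condition] - .data$truth)^2))
    ) |>
    dplyr::ungroup()
  wide <- fits |>
    dplyr::select(dplyr::all_of(c("subject", "condition", terms))) |>
    tidyr::pivot_wider(names_from = "condition", values_from = dplyr::all_of(terms))
  contrasts <- purrr::map_dfr(terms, function(tm) {
    x <- wide[[paste0(tm, "_retrocue")]]
    y <- wide[[paste0(tm, "_control")]]
    res <- wilcoxon_signed_rank(x, y)
    res$term <- tm
    res$median_retrocue <- median(x)
    res$median_control <- median(y)
    res
  })
  structure(list(fits = fits, summary = summary, contrasts = contrasts,
                 design = design, spec = spec, seed = seed),
            class = "rc_recovery")
}

#' @export
print.rc_recovery <- function(x, ...) {
  cat(sprintf("<rc_recovery> %s fits to %s-generated data (%d subjects)\n",
              model_label(x$spec), x$design$family, x$design$n_subjects))
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}
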