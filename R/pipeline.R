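#' Configure the end-to-end analysis
#'
#' @description
#' Bundles everything [run_analysis()] needs: the data (a canonical trial
#' table, or an [experiment_design()] to simulate one), the list of model
#' variants to fit, fitting options, histogram settings and a global seed.
#' When an experiment offers several control conditions, one is selected per
#' experiment in decreasing order of preference: neutral-cue, no-cue,
#' post-cue.
#'
#' @param trials Canonical trial table (omit if `design` is given).
#' @param design An [experiment_design()] to simulate (omit if `trials`).
#' @param models Non-empty list of [model_spec()] objects; the default is the
#'   five variants the pipeline compares.
#' @param options [fit_options()].
#' @param nontarget_bins,nontarget_reps Settings for the chance-corrected
#'   non-target histograms.
#' @param seed Global integer seed.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(trials = NULL, design = NULL,
                            models = list(
                              model_spec("popcode"),
                              model_spec("popcode", with_swaps = TRUE),
                              model_spec("popcode", with_swaps = TRUE, with_guess = TRUE),
                              model_spec("normal_uniform"),
                              model_spec("normal_uniform", with_swaps = TRUE)),
                            options = fit_options(),
                            nontarget_bins = 36L, nontarget_reps = 1000L,
                            seed = 1L) {
  if (is.null(trials) == is.null(design)) {
    abort("give exactly one of `trials` or `design`.")
  }
  if (!is.list(models) || length(models) == 0 ||
      !all(vapply(models, inherits, logical(1), "model_spec"))) {
    abort("`models` must be a non-empty list of model_spec objects.")
  }
  structure(list(trials = trials, design = design, models = models,
                 options = options, nontarget_bins = as.integer(nontarget_bins),
                 nontarget_reps = as.integer(nontarget_reps),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# keep the preferred control kind per experiment: neutral > nocue > postcue
select_control <- function(trials) {
  pref <- c(neutral = 1, nocue = 2, postcue = 3, none = 4)
  keep <- trials |>
    dplyr::filter(.data$condition == "control") |>
    dplyr::distinct(.data$experiment, .data$control_kind) |>
    dplyr::mutate(rank = pref[.data$control_kind]) |>
    dplyr::group_by(.data$experiment) |>
    dplyr::slice_min(.data$rank, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  trials |>
    dplyr::semi_join(keep, by = c("experiment", "control_kind")) |>
    dplyr::bind_rows(dplyr::filter(trials, .data$condition == "retrocue"))
}

#' Mean absolute recall error per data set, in native degrees
#'
#' Each experiment x set-size combination is treated as an independent data
#' set. Errors are `circ_dist(response, target)` converted back to native
#' response degrees via the experiment's feature space.
#'
#' @param trials Canonical trial table.
#' @param spaces Feature-space configuration (defaults to the table's
#'   `"spaces"` attribute).
#' @return A tibble with `experiment`, `set_size`, `condition`, `n_trials`,
#'   `mae_deg`.
#' @export
mean_abs_error <- function(trials, spaces = attr(trials, "spaces")) {
  spaces <- read_space_config(spaces)
  per <- vapply(spaces, function(s) s$period_degrees, numeric(1))
  trials |>
    dplyr::mutate(err = abs(circ_dist(.data$response, .data$target)) *
                    per[.data$experiment] / (2 * pi)) |>
    dplyr::group_by(.data$experiment, .data$set_size, .data$condition) |>
    dplyr::summarise(n_trials = dplyr::n(), mae_deg = mean(.data$err),
                     .groups = "drop")
}

#' Run the full retro-cue analysis
#'
#' @description
#' The end-to-end pipeline over a collated (or synthetic) trial table:
#'
#' 1. mean absolute error per data set (experiment x set size) and condition,
#'    with a paired t test across data sets;
#' 2. per-participant maximum-likelihood fits of every requested model
#'    variant in each condition;
#' 3. pairwise AIC model comparisons (total delta AIC, fraction of
#'    participants favouring each model, sign tests);
#' 4. condition contrasts of the fitted parameters: medians with bootstrap
#'    standard errors and Wilcoxon signed-rank tests across participants;
#' 5. z-scored cross-experiment correlations between median parameters of
#'    the population-coding swap model (gain vs width, width vs swap rate,
#'    gain vs swap rate) with Pearson r and ANCOVA on condition;
#' 6. chance-corrected non-target histograms per condition.
#'
#' Any stage failure aborts with an error naming the stage; stages completed
#' so far are attached to the error condition as `partial`.
#'
#' @param config An [analysis_config()].
#' @return An object of class `rc_bundle`: list with `trials_summary`,
#'   `mae`, `mae_test`, `fits`, `comparisons`, `contrasts`, `correlations`,
#'   `nontarget`, and `provenance` (seed, models, options echo).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  done <- list()
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      abort(sprintf("analysis stage '%s' failed: %s", name, conditionMessage(e)),
            partial = done, parent = e)
    })
  }
  trials <- stage("data", {
    tr <- if (!is.null(config$design)) generate_experiment(config$design) else config$trials
    validate_trials(tr)
    select_control(tr)
  })
  spaces <- attr(config$trials %||% trials, "spaces") %||%
    setNames(as.list(rep(360, length(unique(trials$experiment)))),
             unique(trials$experiment))

  done$mae <- stage("mae", mean_abs_error(trials, spaces))
  done$mae_test <- stage("mae", {
    wide <- tidyr::pivot_wider(done$mae, id_cols = c("experiment", "set_size"),
                               names_from = "condition", values_from = "mae_deg")
    if (nrow(wide) >= 2) paired_t(wide$retrocue, wide$control) else NULL
  })

  done$fits <- stage("fits", {
    purrr::map(config$models, function(m) {
      fit_participants(trials, m, config$options, seed = config$seed)
    }) |> setNames(vapply(config$models, model_label, character(1)))
  })

  done$comparisons <- stage("comparisons", {
    labels <- names(done$fits)
    if (length(labels) < 2) NULL else {
      pairs <- utils::combn(labels, 2, simplify = FALSE)
      purrr::map_dfr(pairs, function(pr) {
        glance(compare_models(done$fits[[pr[1]]], done$fits[[pr[2]]]))
      })
    }
  })

  done$contrasts <- stage("contrasts", {
    purrr::imap_dfr(done$fits, function(ft, label) {
      terms <- intersect(c("rmax", "fwhm", "kappa_prime", "pswap", "pguess"),
                         names(ft))
      wide <- ft |>
        dplyr::select(dplyr::all_of(c("experiment", "subject", "set_size",
                                      "condition", terms))) |>
        tidyr::pivot_wider(names_from = "condition",
                           values_from = dplyr::all_of(terms),
                           names_sep = "@")
      purrr::map_dfr(terms, function(tm) {
        x <- wide[[paste0(tm, "@retrocue")]]
        y <- wide[[paste0(tm, "@control")]]
        ok <- complete.cases(x, y)
        res <- wilcoxon_signed_rank(x[ok], y[ok])
        tibble::tibble(model = label, term = tm,
                       median_retrocue = median(x[ok]),
                       se_retrocue = bootstrap_median_se(x[ok], seed = config$seed),
                       median_control = median(y[ok]),
                       se_control = bootstrap_median_se(y[ok], seed = config$seed),
                       p_value = res$p_value, n = res$n)
      })
    })
  })

  done$correlations <- stage("correlations", {
    lab <- "popcode+swap"
    med <- if (lab %in% names(done$fits)) {
      done$fits[[lab]] |>
        dplyr::group_by(.data$experiment, .data$set_size, .data$condition) |>
        dplyr::summarise(dplyr::across(dplyr::all_of(c("rmax", "fwhm", "pswap")),
                                       median), .groups = "drop")
    } else NULL
    if (is.null(med) || nrow(med) < 4) NULL else {
      purrr::map_dfr(list(c("rmax", "fwhm"), c("fwhm", "pswap"), c("rmax", "pswap")),
                     function(pr) {
        res <- pearson_ancova(med[[pr[1]]], med[[pr[2]]], med$condition)
        dplyr::bind_cols(tibble::tibble(x = pr[1], y = pr[2]), res)
      })
    }
  })

  done$nontarget <- stage("nontarget", {
    if (all(trials$set_size < 2)) NULL else {
      conds <- unique(trials$condition)
      setNames(lapply(conds, function(cc) {
        chance_corrected_hist(trials[trials$condition == cc, , drop = FALSE],
                              n_bins = config$nontarget_bins,
                              reps = config$nontarget_reps,
                              seed = config$seed)
      }), conds)
    }
  })

  done$trials_summary <- trials |>
    dplyr::count(.data$experiment, .data$condition, .data$set_size,
                 name = "n_trials")
  done$provenance <- list(
    seed = config$seed,
    models = vapply(config$models, model_label, character(1)),
    n_starts = config$options$n_starts,
    density_method = config$options$settings$method,
    generated = !is.null(config$design)
  )
  structure(done, class = "rc_bundle")
}

#' @export
print.rc_bundle <- function(x, ...) {
  cat("<rc_bundle> retro-cue analysis results\n")
  cat(sprintf("  data sets: %d; models: %s\n",
              nrow(unique(x$mae[c("experiment", "set_size")])),
              paste(x$provenance$models, collapse = ", ")))
  cat(sprintf("  mean absolute error (deg): retrocue %.1f vs control %.1f%s\n",
              mean(x$mae$mae_deg[x$mae$condition == "retrocue"]),
              mean(x$mae$mae_deg[x$mae$condition == "control"]),
              if (!is.null(x$mae_test)) {
                sprintf(" (paired t p = %.3g)", x$mae_test$p_value)
              } else ""))
  if (!is.null(x$contrasts)) {
    cat("  condition contrasts (medians, retrocue vs control):\n")
    print(as.data.frame(x$contrasts[c("model", "term", "median_retrocue",
                                      "median_control", "p_value")]), digits = 3)
  }
  invisible(x)
}

#' Write an analysis bundle to delimited text files
#'
#' Writes each result table of an [run_analysis()] bundle (`mae.csv`,
#' `fits_<model>.csv`, `comparisons.csv`, `contrasts.csv`,
#' `correlations.csv`, `nontarget_<condition>.csv`, `provenance.csv`) into a
#' directory.
#'
#' @param bundle An `rc_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "rc_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tab, name) {
    if (!is.null(tab)) {
      readr::write_csv(tibble::as_tibble(tab), file.path(dir, name),
                       progress = FALSE)
    }
  }
  w(bundle$mae, "mae.csv")
  w(bundle$mae_test, "mae_test.csv")
  for (nm in names(bundle$fits)) {
    w(dplyr::select(bundle$fits[[nm]], -dplyr::any_of("fit")),
      paste0("fits_", gsub("[^a-z_]+", "_", nm), ".csv"))
  }
  w(bundle$comparisons, "comparisons.csv")
  w(bundle$contrasts, "contrasts.csv")
  w(bundle$correlations, "correlations.csv")
  for (nm in names(bundle$nontarget)) {
    w(bundle$nontarget[[nm]], paste0("nontarget_", nm, ".csv"))
  }
  w(tibble::tibble(key = names(unlist(bundle$provenance)),
                   value = as.character(unlist(bundle$provenance))),
    "provenance.csv")
  invisible(dir)
}
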