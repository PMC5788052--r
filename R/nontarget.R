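#' Chance-corrected histogram of deviations from non-target values
#'
#' @description
#' Swap errors show up as a central tendency in the distribution of response
#' deviations from *non-target* feature values. Because many experiments
#' enforce minimum separations between array items, that distribution is
#' biased even in the absence of swaps; it is corrected for chance by a
#' randomization procedure: within each subject x condition group, the
#' deviations of non-target values from target values are randomly shuffled
#' across (trial, slot) pairs and added back to the target values to generate
#' simulated non-targets, and deviations of responses from these simulated
#' non-targets are recorded. Averaged over `reps` repetitions this estimates
#' the chance distribution, which is subtracted from the observed one.
#'
#' Trials with set size 1 carry no non-targets and are excluded (with a
#' message). The observed and chance histograms are normalized densities, so
#' the corrected histogram integrates to 0 and is flat at 0 when non-targets
#' have no influence on responses.
#'
#' @param trials Canonical trial table (internal radians).
#' @param n_bins Number of histogram bins over `[-pi, pi)` (default 36,
#'   i.e. 10 degrees of internal angle).
#' @param reps Number of shuffle repetitions (default 1000).
#' @param seed Optional integer seed.
#' @return A tibble of class `rc_hist` with columns `bin_center`,
#'   `observed_density`, `chance_density`, `corrected_density`; `reps`,
#'   `seed`, the number of trials used and excluded are attached as
#'   attributes.
#' @export
chance_corrected_hist <- function(trials, n_bins = 36L, reps = 1000L,
                                  seed = NULL) {
  validate_trials(trials)
  stopifnot(reps >= 1, n_bins >= 4)
  excluded <- sum(trials$set_size < 2)
  if (excluded > 0) {
    inform(sprintf("excluding %d trial(s) with set size 1 (no non-targets)", excluded))
    trials <- trials[trials$set_size >= 2, , drop = FALSE]
  }
  if (nrow(trials) == 0) abort("no trials with non-targets.")
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  binw <- 2 * pi / n_bins
  centers <- breaks[-1] - binw / 2
  nt <- nontarget_matrix(trials)
  slots <- which(!is.na(nt), arr.ind = TRUE)           # (trial, slot) pairs
  tgt <- trials$target[slots[, 1]]
  rsp <- trials$response[slots[, 1]]
  dev_nt <- wrap_angle(nt[slots] - tgt)                # target -> non-target deviations
  grp <- paste(trials$subject, trials$condition)[slots[, 1]]

  hist_density <- function(v) {
    tabulate(findInterval(v, breaks, all.inside = TRUE), n_bins) /
      (length(v) * binw)
  }
  observed <- hist_density(wrap_angle(rsp - nt[slots]))

  chance_of_rep <- function() {
    d_perm <- unsplit(lapply(split(dev_nt, grp), sample), grp)
    hist_density(wrap_angle(rsp - wrap_angle(tgt + d_perm)))
  }
  run <- function() {
    acc <- 0
    for (r in seq_len(reps)) acc <- acc + chance_of_rep()
    acc / reps
  }
  chance <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  out <- tibble::tibble(bin_center = centers, observed_density = observed,
                        chance_density = chance,
                        corrected_density = observed - chance)
  class(out) <- c("rc_hist", class(out))
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  attr(out, "n_deviations") <- length(dev_nt)
  attr(out, "n_excluded") <- excluded
  out
}

#' Export a corrected non-target histogram as delimited text
#'
#' @param hist An `rc_hist` tibble from [chance_corrected_hist()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hist <- function(hist, path) {
  stopifnot(inherits(hist, "rc_hist"))
  readr::write_csv(tibble::as_tibble(hist), path, progress = FALSE)
  invisible(path)
}
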