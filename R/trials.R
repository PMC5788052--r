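#' The canonical trial table
#'
#' @description
#' All analyses in retropop operate on a single canonical schema for delayed
#' estimation trials, one row per trial:
#'
#' * `subject`, `experiment` — identifiers (character);
#' * `condition` — `"retrocue"` or `"control"`;
#' * `control_kind` — `"neutral"`, `"nocue"`, `"postcue"`, or `"none"`
#'   (for retro-cue rows);
#' * `set_size` — number of items in the memory array (positive integer);
#' * `target` — probed feature value, internal radians;
#' * `nontarget_1 ... nontarget_k` — unprobed feature values, internal
#'   radians, `NA` in unused slots (a row with set size `s` has exactly
#'   `s - 1` non-missing non-targets);
#' * `response` — reported feature value, internal radians.
#'
#' On disk the same schema is stored in native degrees (comma- or
#' tab-separated, auto-detected) together with a feature-space configuration;
#' [read_trials()] converts to internal radians and validates, and
#' [write_trials()] is its inverse. Synthetic data from
#' [generate_experiment()] use the identical schema, so simulated and real
#' data are interchangeable everywhere.
#'
#' @param trials A data frame in the canonical schema.
#' @return `validate_trials()` returns its input invisibly, or aborts with a
#'   message naming the offending rows.
#' @export
validate_trials <- function(trials) {
  req <- c("subject", "experiment", "condition", "set_size", "target", "response")
  missing_cols <- setdiff(req, names(trials))
  if (length(missing_cols) > 0) {
    abort(paste0("trial table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  nt_cols <- nontarget_cols(trials)
  bad <- function(rows, why) {
    if (length(rows) > 0) {
      abort(sprintf("invalid trial row(s) %s: %s",
                    paste(head(rows, 10), collapse = ", "), why))
    }
  }
  bad(which(!is.finite(trials$set_size) | trials$set_size < 1 |
              trials$set_size != round(trials$set_size)),
      "set_size must be a positive integer")
  bad(which(!is.finite(trials$target) | !is.finite(trials$response)),
      "target and response must be finite angles")
  if (any(!nzchar(as.character(trials$subject))) ||
      any(!nzchar(as.character(trials$experiment)))) {
    abort("subject and experiment labels must be non-empty")
  }
  bad(which(!trials$condition %in% c("retrocue", "control")),
      "condition must be 'retrocue' or 'control'")
  if ("control_kind" %in% names(trials)) {
    bad(which(!trials$control_kind %in% c("neutral", "nocue", "postcue", "none")),
        "control_kind must be one of neutral, nocue, postcue, none")
  }
  n_nt <- if (length(nt_cols) > 0) {
    rowSums(!is.na(as.matrix(trials[nt_cols])))
  } else rep(0L, nrow(trials))
  bad(which(n_nt != trials$set_size - 1),
      "number of non-missing nontarget_* values must equal set_size - 1")
  ang <- c(trials$target, trials$response,
           unlist(trials[nt_cols], use.names = FALSE))
  ang <- ang[!is.na(ang)]
  if (any(ang < -pi - 1e-9 | ang >= pi + 1e-9)) {
    abort("angles must be internal radians in [-pi, pi); use read_trials() to convert degrees")
  }
  invisible(trials)
}

nontarget_cols <- function(trials) {
  grep("^nontarget_[0-9]+$", names(trials), value = TRUE)
}

# matrix of non-target angles (rows = trials), NA in unused slots
nontarget_matrix <- function(trials) {
  cols <- nontarget_cols(trials)
  if (length(cols) == 0) return(matrix(numeric(0), nrow = nrow(trials), ncol = 0))
  as.matrix(trials[cols])
}

#' Read a trial table from delimited text
#'
#' Reads a canonical trial table stored in native degrees, auto-detecting
#' comma or tab separation, converts all angles to internal radians using the
#' per-experiment feature-space configuration, validates the result, and
#' (when a `valid` column is present) retains only valid retro-cue trials.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param space_config Feature-space configuration accepted by
#'   [read_space_config()].
#' @return A tibble in the canonical schema (internal radians), with the
#'   feature-space list attached as attribute `"spaces"`.
#' @export
read_trials <- function(path, space_config) {
  spaces <- read_space_config(space_config)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(sprintf("unparseable values at row(s) %s of %s",
                  paste(head(unique(prob$row), 10), collapse = ", "), path))
  }
  req <- c("subject", "experiment", "condition", "set_size", "target", "response")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  unknown <- setdiff(unique(raw$experiment), names(spaces))
  if (length(unknown) > 0) {
    abort(paste0("no feature space configured for experiment(s): ",
                 paste(unknown, collapse = ", ")))
  }
  out <- tibble::as_tibble(raw)
  out$subject <- as.character(out$subject)
  out$experiment <- as.character(out$experiment)
  if (!"control_kind" %in% names(out)) out$control_kind <- "none"
  per <- vapply(spaces, function(s) s$period_degrees, numeric(1))[out$experiment]
  scale <- 2 * pi / per
  for (col in c("target", "response", nontarget_cols(out))) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA_real_,
                         wrap_angle_na(out[[col]] * scale))
  }
  if ("valid" %in% names(out)) {
    keep <- out$condition != "retrocue" | out$valid %in% c(1, TRUE, "1", "TRUE")
    out <- out[keep, , drop = FALSE]
    out$valid <- NULL
  }
  validate_trials(out)
  attr(out, "spaces") <- spaces
  out
}

# wrap that passes NA through (unused non-target slots)
wrap_angle_na <- function(x) {
  out <- x
  ok <- !is.na(x)
  out[ok] <- wrap_angle(x[ok])
  out
}

#' Write a trial table to delimited text
#'
#' Inverse of [read_trials()]: converts internal radians back to native
#' degrees using the supplied feature-space configuration and writes a CSV.
#'
#' @param trials Canonical trial table (internal radians).
#' @param path Output file path.
#' @param space_config Configuration accepted by [read_space_config()];
#'   defaults to the `"spaces"` attribute of `trials`.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, space_config = attr(trials, "spaces")) {
  validate_trials(trials)
  spaces <- read_space_config(space_config)
  per <- vapply(spaces, function(s) s$period_degrees, numeric(1))[trials$experiment]
  out <- trials
  for (col in c("target", "response", nontarget_cols(trials))) {
    out[[col]] <- out[[col]] * per / (2 * pi)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
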